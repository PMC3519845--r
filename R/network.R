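# Core domain types: typed nodes, typed/signed/optionally-directed relations,
# and the interaction network container every pipeline stage operates on.

#' Controlled vocabularies for network entities and relations
#'
#' `node_kinds()` lists the five entity classes an interactome node may take;
#' `relation_types()` lists the supported relation classes and
#' `relation_effects()` the sign of a relation's effect.
#'
#' @return A character vector of allowed values.
#' @export
node_kinds <- function() {
  c("protein", "small_molecule", "functional_class", "complex", "cell_process")
}

#' @rdname node_kinds
#' @export
relation_types <- function() {
  c("binding", "protein_modification", "direct_regulation", "expression",
    "promoter_binding", "mol_synthesis", "mol_transport", "regulation",
    "chemical_reaction", "unknown")
}

#' @rdname node_kinds
#' @export
relation_effects <- function() {
  c("positive", "negative", "unknown")
}

# Default directedness by relation type. binding is physical and symmetric;
# promoter_binding and expression are inherently directed; the rest default
# to directed regulatory semantics except `unknown`.
.default_directed <- c(
  binding = FALSE, protein_modification = TRUE, direct_regulation = TRUE,
  expression = TRUE, promoter_binding = TRUE, mol_synthesis = TRUE,
  mol_transport = TRUE, regulation = TRUE, chemical_reaction = TRUE,
  unknown = FALSE
)

#' Construct a validated interaction network
#'
#' The container for a typed interactome: a node table (id, kind, expression
#' status) and a relation table (source, target, relation type, effect sign,
#' directedness, free-text references). Undirected relations are
#' canonicalized so the lexicographically smaller id is stored as the source,
#' making relation identity well defined. Self-loops and duplicate canonical
#' (source, target, rel_type) triples are rejected: the downstream
#' shortest-path-tree and neighborhood-component statistics are defined on
#' simple graphs.
#'
#' @param nodes `NULL`, a character vector of node ids, or a data frame with
#'   columns `id` and optionally `kind` (see [node_kinds()]; default
#'   `"protein"`) and `de_status` (`"up"`, `"down"` or `"none"`). When `NULL`
#'   the node set is taken from the relations.
#' @param relations A data frame with columns `source` and `target`, and
#'   optionally `rel_type` (see [relation_types()]; default `"unknown"`),
#'   `effect` (default `"unknown"`), `directed` (logical; default depends on
#'   `rel_type`) and `references` (character; `"|"`-separated citations).
#' @param name Network name (free text).
#' @return An object of class `interaction_network` with elements `nodes`,
#'   `relations` and `name`.
#' @examples
#' net <- interaction_network(
#'   relations = data.frame(source = c("A", "B"), target = c("B", "C"),
#'                          rel_type = c("binding", "regulation")))
#' net
#' @export
interaction_network <- function(nodes = NULL, relations = NULL, name = "") {
  if (is.null(relations)) {
    relations <- data.frame(source = character(), target = character(),
                            rel_type = character(), effect = character(),
                            directed = logical(), references = character(),
                            stringsAsFactors = FALSE)
  }
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(relations)))
    stop("relations need 'source' and 'target' columns", call. = FALSE)
  relations$source <- as.character(relations$source)
  relations$target <- as.character(relations$target)
  if (is.null(relations$rel_type)) relations$rel_type <- "unknown"
  relations$rel_type <- as.character(relations$rel_type)
  bad_type <- setdiff(unique(relations$rel_type), relation_types())
  if (length(bad_type))
    stop("unknown relation type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  if (is.null(relations$effect)) relations$effect <- "unknown"
  relations$effect <- as.character(relations$effect)
  bad_eff <- setdiff(unique(relations$effect), relation_effects())
  if (length(bad_eff))
    stop("unknown effect value(s): ", paste(bad_eff, collapse = ", "),
         call. = FALSE)
  if (is.null(relations$directed))
    relations$directed <- unname(.default_directed[relations$rel_type])
  relations$directed <- as.logical(relations$directed)
  if (anyNA(relations$directed))
    stop("'directed' must be TRUE/FALSE", call. = FALSE)
  if (is.null(relations$references)) relations$references <- ""
  relations$references <- as.character(relations$references)
  relations$references[is.na(relations$references)] <- ""
  relations <- relations[c("source", "target", "rel_type", "effect",
                           "directed", "references")]

  if (any(relations$source == relations$target)) {
    loops <- unique(relations$source[relations$source == relations$target])
    stop("self-loop(s) not allowed: ", paste(loops, collapse = ", "),
         call. = FALSE)
  }
  # type-level directedness constraints
  if (any(relations$rel_type == "binding" & relations$directed))
    stop("'binding' relations must be undirected", call. = FALSE)
  if (any(relations$rel_type %in% c("promoter_binding", "expression") &
          !relations$directed))
    stop("'promoter_binding' and 'expression' relations must be directed",
         call. = FALSE)

  # canonicalize undirected pairs: smaller id first
  flip <- !relations$directed & relations$source > relations$target
  if (any(flip)) {
    tmp <- relations$source[flip]
    relations$source[flip] <- relations$target[flip]
    relations$target[flip] <- tmp
  }
  key <- paste(relations$source, relations$target, relations$rel_type,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate relation(s) after canonicalization: ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }

  rel_ids <- unique(c(relations$source, relations$target))
  if (is.null(nodes)) {
    nodes <- data.frame(id = rel_ids, stringsAsFactors = FALSE)
  } else if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes))
    stop("nodes need an 'id' column", call. = FALSE)
  nodes$id <- as.character(nodes$id)
  if (any(!nzchar(nodes$id)) || anyNA(nodes$id))
    stop("node ids must be non-empty", call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  if (is.null(nodes$kind)) nodes$kind <- rep("protein", nrow(nodes))
  nodes$kind <- as.character(nodes$kind)
  nodes$kind[is.na(nodes$kind) | !nzchar(nodes$kind)] <- "protein"
  bad_kind <- setdiff(unique(nodes$kind), node_kinds())
  if (length(bad_kind))
    stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  if (is.null(nodes$de_status)) nodes$de_status <- rep("none", nrow(nodes))
  nodes$de_status <- as.character(nodes$de_status)
  bad_de <- setdiff(unique(nodes$de_status), c("up", "down", "none"))
  if (length(bad_de))
    stop("de_status must be 'up', 'down' or 'none'", call. = FALSE)
  nodes <- nodes[c("id", "kind", "de_status")]

  missing <- setdiff(rel_ids, nodes$id)
  if (length(missing))
    stop("relation endpoint(s) not in node table: ",
         paste(missing, collapse = ", "), call. = FALSE)

  nodes <- nodes[order(nodes$id), , drop = FALSE]
  relations <- relations[order(relations$source, relations$target,
                               relations$rel_type), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(relations) <- NULL
  structure(list(nodes = nodes, relations = relations,
                 name = as.character(name)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network",
      if (nzchar(x$name)) paste0("'", x$name, "'") else "", "\n")
  cat("  nodes:     ", nrow(x$nodes), "\n")
  kt <- table(x$nodes$kind)
  cat("    kinds:   ", paste(names(kt), kt, sep = "=", collapse = ", "), "\n")
  det <- table(factor(x$nodes$de_status, c("up", "down", "none")))
  cat("    DE:      ", det[["up"]], "up,", det[["down"]], "down\n")
  cat("  relations: ", nrow(x$relations),
      sprintf("(%d distinct pairs)", nrow(edge_pairs(x))), "\n")
  invisible(x)
}

#' Distinct undirected node pairs of a network
#'
#' The simple undirected topology used by all graph statistics: parallel
#' relations between the same pair (different relation types or directions)
#' collapse to one topological edge.
#'
#' @param net An [interaction_network()].
#' @return A two-column character data frame (`a`, `b`) with `a < b`, one row
#'   per distinct pair.
#' @export
edge_pairs <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  a <- pmin(net$relations$source, net$relations$target)
  b <- pmax(net$relations$source, net$relations$target)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

# Named adjacency list over the simple undirected topology; every node is
# present (isolated nodes map to character(0)); neighbor vectors sorted.
adjacency_list <- function(net) {
  ids <- net$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  ep <- edge_pairs(net)
  if (nrow(ep)) {
    nb <- split(c(ep$b, ep$a), c(ep$a, ep$b))
    adj[names(nb)] <- lapply(nb, sort)
  }
  adj
}

#' Convert a network to an igraph object
#'
#' Returns the simple undirected topology (distinct neighbor pairs, no
#' attributes beyond vertex names); this is the view on which degrees,
#' shortest paths and neighborhood components are computed.
#'
#' @param net An [interaction_network()].
#' @return An undirected simple [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  ep <- edge_pairs(net)
  igraph::graph_from_data_frame(ep, directed = FALSE,
                                vertices = net$nodes$id)
}

# Subset a network to a node set and/or a set of unordered pairs, keeping
# original relation attributes. pairs: data.frame(a, b) or NULL (keep all
# relations among keep_nodes).
subnetwork <- function(net, keep_nodes, pairs = NULL, name = net$name) {
  keep_nodes <- unique(keep_nodes)
  rel <- net$relations
  if (is.null(pairs)) {
    sel <- rel$source %in% keep_nodes & rel$target %in% keep_nodes
  } else {
    want <- paste(pairs$a, pairs$b, sep = "\r")
    key <- paste(pmin(rel$source, rel$target),
                 pmax(rel$source, rel$target), sep = "\r")
    sel <- key %in% want
  }
  nodes <- net$nodes[net$nodes$id %in% keep_nodes, , drop = FALSE]
  interaction_network(nodes, rel[sel, , drop = FALSE], name = name)
}

#' Set node differential-expression status from a DE gene set
#'
#' @param net An [interaction_network()].
#' @param deset A [de_gene_set()].
#' @return The network with `de_status` set to `"up"`/`"down"`/`"none"`.
#' @export
apply_de_status <- function(net, deset) {
  stopifnot(inherits(net, "interaction_network"), inherits(deset, "de_gene_set"))
  net$nodes$de_status <- rep("none", nrow(net$nodes))
  net$nodes$de_status[net$nodes$id %in% deset$up] <- "up"
  net$nodes$de_status[net$nodes$id %in% deset$down] <- "down"
  net
}
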