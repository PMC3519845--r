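# Network construction: shortest-path networks from seed genes to biological
# groups, subtraction of the DE-anchored subnetwork, and summary statistics.

#' Define a biological group
#'
#' A named container of interactome entities (a biological process, a
#' functional class such as an enzyme family, or a complex) that seeds are
#' connected to by shortest paths.
#'
#' @param name Group name.
#' @param members Character vector of node ids (non-empty).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, members) {
  members <- unique(as.character(members))
  if (!length(members)) stop("group members must be non-empty", call. = FALSE)
  structure(list(name = as.character(name), members = members),
            class = "group_spec")
}

#' Build a shortest-path network from seeds to biological groups
#'
#' For each seed \eqn{s} and each group \eqn{G}, finds the minimum
#' unweighted shortest-path distance \eqn{d^*} from \eqn{s} to any member of
#' \eqn{G} on the undirected view of the interactome (direction and effect
#' are edge attributes only, never path constraints). If \eqn{d^* \le}
#' `max_len`, *all* shortest paths from \eqn{s} to *every* member at
#' distance \eqn{d^*} are included — this makes the output deterministic and
#' independent of any tie-breaking path choice. The result is the union of
#' all included path edges with their original relation attributes, plus the
#' incident nodes. Seeds with no group member within `max_len` contribute
#' nothing (reported via a message). A seed that is itself a group member
#' contributes only itself (\eqn{d^* = 0}).
#'
#' @param interactome An [interaction_network()].
#' @param seeds Character vector of seed node ids (must exist in the
#'   interactome).
#' @param groups List of [group_spec()] objects (members not present in the
#'   interactome are ignored; a group with no present member contributes
#'   nothing).
#' @param max_len Maximum path length in edges (default 4): bounds runtime
#'   and path dilution on dense interactomes.
#' @return An [interaction_network()] containing the union of all included
#'   shortest paths.
#' @export
shortest_path_network <- function(interactome, seeds, groups, max_len = 4) {
  stopifnot(inherits(interactome, "interaction_network"), max_len >= 1)
  seeds <- unique(as.character(seeds))
  unknown <- setdiff(seeds, interactome$nodes$id)
  if (length(unknown))
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!length(groups)) stop("empty groups list", call. = FALSE)
  if (inherits(groups, "group_spec")) groups <- list(groups)

  g <- as_igraph(interactome)
  ids <- igraph::V(g)$name
  keep_nodes <- character(0)
  keep_pairs <- character(0)
  unreached <- 0L

  for (s in seeds) {
    d <- igraph::distances(g, v = s)[1, ]
    for (grp in groups) {
      members <- intersect(grp$members, ids)
      if (!length(members)) next
      dm <- d[members]
      dstar <- suppressWarnings(min(dm))
      if (!is.finite(dstar) || dstar > max_len) {
        unreached <- unreached + 1L
        next
      }
      nearest <- members[dm == dstar]
      if (dstar == 0) {
        keep_nodes <- c(keep_nodes, s)
        next
      }
      for (m in nearest) {
        paths <- igraph::all_shortest_paths(g, from = s, to = m)$res
        for (p in paths) {
          vp <- names(p)
          keep_nodes <- c(keep_nodes, vp)
          a <- vp[-length(vp)]
          b <- vp[-1]
          keep_pairs <- c(keep_pairs,
                          paste(pmin(a, b), pmax(a, b), sep = "\r"))
        }
      }
    }
  }
  if (unreached)
    message(unreached, " seed/group pair(s) beyond max_len = ", max_len,
            " contributed nothing")
  keep_pairs <- unique(keep_pairs)
  pairs <- if (length(keep_pairs)) {
    sp <- strsplit(keep_pairs, "\r", fixed = TRUE)
    data.frame(a = vapply(sp, `[`, "", 1), b = vapply(sp, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  }
  subnetwork(interactome, unique(keep_nodes), pairs,
             name = paste0(interactome$name, ":sp"))
}

#' Subtract the DE-anchored subnetwork
#'
#' Retains exactly those relations in which at least one of the two
#' endpoints is differentially expressed (up- or downregulated), and exactly
#' the nodes incident to a retained relation. Node `de_status` is set from
#' the DE gene set. The operation is idempotent and always returns an edge
#' subset of its input.
#'
#' @param net An [interaction_network()].
#' @param deset A [de_gene_set()].
#' @return The subtracted [interaction_network()] (possibly empty).
#' @export
subtract_network <- function(net, deset) {
  stopifnot(inherits(net, "interaction_network"), inherits(deset, "de_gene_set"))
  de <- de_genes(deset)
  rel <- net$relations
  sel <- rel$source %in% de | rel$target %in% de
  if (!any(sel)) message("subtraction produced an empty network")
  kept <- rel[sel, , drop = FALSE]
  keep_nodes <- unique(c(kept$source, kept$target))
  out <- subnetwork(net, keep_nodes, NULL, name = paste0(net$name, ":sub"))
  # subnetwork() keeps all relations among kept nodes; restrict to anchored
  sel2 <- out$relations$source %in% de | out$relations$target %in% de
  out$relations <- out$relations[sel2, , drop = FALSE]
  rownames(out$relations) <- NULL
  apply_de_status(out, deset)
}

#' Summarize a network
#'
#' Node/edge counts, average degree and DE composition. Degree counts
#' distinct neighbors on the simple undirected topology; the average degree
#' is \eqn{2E/V} reported both as a real number and truncated toward zero
#' (the integer form conventional in network reports).
#'
#' @param net An [interaction_network()].
#' @param deset Optional [de_gene_set()]; when supplied, `n_up`/`n_down`
#'   count network nodes in each direction.
#' @return An object of class `network_summary`: a list with `n_nodes`,
#'   `n_edges`, `avg_degree`, `avg_degree_int`, `n_up`, `n_down`,
#'   `degree_by_node`.
#' @examples
#' tri <- interaction_network(relations = data.frame(
#'   source = c("A", "A", "B"), target = c("B", "C", "C")))
#' summarize_network(tri)$avg_degree  # 2
#' @export
summarize_network <- function(net, deset = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  n_nodes <- nrow(net$nodes)
  ep <- edge_pairs(net)
  n_edges <- nrow(ep)
  deg <- lengths(adjacency_list(net))
  avg <- if (n_nodes > 0) 2 * n_edges / n_nodes else 0
  n_up <- n_down <- 0L
  if (!is.null(deset)) {
    n_up <- sum(net$nodes$id %in% deset$up)
    n_down <- sum(net$nodes$id %in% deset$down)
  } else {
    n_up <- sum(net$nodes$de_status == "up")
    n_down <- sum(net$nodes$de_status == "down")
  }
  structure(list(n_nodes = n_nodes, n_edges = n_edges, avg_degree = avg,
                 avg_degree_int = trunc(avg), n_up = n_up, n_down = n_down,
                 degree_by_node = deg),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  average degree: %.2f (reported as %d)\n",
              x$avg_degree, x$avg_degree_int))
  cat(sprintf("  DE nodes: %d up, %d down\n", x$n_up, x$n_down))
  invisible(x)
}
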