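# Readers/writers for the plain-text formats the pipeline touches:
# SIF and attributed-TSV edge lists, expression tables, GMT annotation sets,
# and ranked hub-score tables. All files are UTF-8; '#' lines are comments.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Read an interaction network from SIF or attributed TSV
#'
#' SIF lines are `node1 relation node2` (whitespace-separated). The TSV
#' dialect carries full relation attributes with header columns
#' `source, rel_type, effect, directed, target, references`. Unknown
#' relation-type strings map to `"unknown"` with a warning; in SIF, node
#' kinds default to `"protein"` and directedness follows the relation-type
#' defaults. An optional companion node table (`nodes_path`, TSV with
#' columns `id, kind, de_status`) supplies node attributes and isolated
#' nodes, which the edge formats cannot carry.
#'
#' @param path Path to the edge file.
#' @param dialect `"sif"` or `"tsv"`.
#' @param nodes_path Optional path to a node-attribute TSV.
#' @param name Network name; defaults to the file name.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, dialect = c("sif", "tsv"), nodes_path = NULL,
                         name = basename(path)) {
  dialect <- match.arg(dialect)
  lines <- .read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]

  if (dialect == "sif") {
    parts <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(parts)
    if (any(nf != 3))
      stop("malformed SIF line ", lineno[which(nf != 3)[1]],
           ": expected 'node relation node'", call. = FALSE)
    rel <- data.frame(source = vapply(parts, `[`, "", 1),
                      rel_type = vapply(parts, `[`, "", 2),
                      target = vapply(parts, `[`, "", 3),
                      stringsAsFactors = FALSE)
    unk <- !(rel$rel_type %in% relation_types())
    if (any(unk)) {
      warning("unknown relation type(s) mapped to 'unknown': ",
              paste(unique(rel$rel_type[unk]), collapse = ", "),
              call. = FALSE)
      rel$rel_type[unk] <- "unknown"
    }
  } else {
    if (!length(lines)) stop("empty TSV network file: ", path, call. = FALSE)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("source", "rel_type", "effect", "directed", "target")
    if (!all(need %in% header))
      stop("TSV network header must contain: ",
           paste(need, collapse = ", "), call. = FALSE)
    body <- lines[-1]
    lineno <- lineno[-1]
    cells <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(cells)
    short <- nf < length(header) - ("references" %in% header)
    if (any(short))
      stop("malformed TSV line ", lineno[which(short)[1]],
           ": expected ", length(header), " tab-separated fields",
           call. = FALSE)
    get <- function(col) vapply(cells, function(x) {
      i <- match(col, header)
      if (i <= length(x)) x[i] else ""
    }, "")
    rel <- data.frame(source = get("source"), rel_type = get("rel_type"),
                      effect = get("effect"), directed = get("directed"),
                      target = get("target"), stringsAsFactors = FALSE)
    rel$references <- if ("references" %in% header) get("references") else ""
    unk <- !(rel$rel_type %in% relation_types())
    if (any(unk)) {
      warning("unknown relation type(s) mapped to 'unknown': ",
              paste(unique(rel$rel_type[unk]), collapse = ", "),
              call. = FALSE)
      rel$rel_type[unk] <- "unknown"
    }
    dirv <- toupper(rel$directed) %in% c("TRUE", "T", "1")
    ndir <- toupper(rel$directed) %in% c("FALSE", "F", "0")
    if (any(!(dirv | ndir)))
      stop("malformed TSV line ", lineno[which(!(dirv | ndir))[1]],
           ": 'directed' must be TRUE/FALSE", call. = FALSE)
    rel$directed <- dirv
  }

  nodes <- NULL
  if (!is.null(nodes_path)) {
    nt <- utils::read.delim(nodes_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!"id" %in% names(nt))
      stop("node table needs an 'id' column", call. = FALSE)
    nodes <- nt
    extra <- setdiff(unique(c(rel$source, rel$target)), nodes$id)
    if (length(extra))
      stop("edge file references node(s) absent from node table: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  interaction_network(nodes, rel, name = name)
}

#' Write an interaction network to SIF or attributed TSV
#'
#' Inverse of [read_network()]: `read_network(write_network(net, p), p)`
#' reproduces the node set and relation attributes exactly when a
#' `nodes_path` companion table is written (the edge formats alone cannot
#' carry node kinds or isolated nodes).
#'
#' @inheritParams read_network
#' @param net An [interaction_network()].
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, dialect = c("sif", "tsv"),
                          nodes_path = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  dialect <- match.arg(dialect)
  rel <- net$relations
  if (dialect == "sif") {
    lines <- sprintf("%s %s %s", rel$source, rel$rel_type, rel$target)
  } else {
    lines <- c(paste(c("source", "rel_type", "effect", "directed", "target",
                       "references"), collapse = "\t"),
               sprintf("%s\t%s\t%s\t%s\t%s\t%s", rel$source, rel$rel_type,
                       rel$effect, rel$directed, rel$target, rel$references))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  if (!is.null(nodes_path)) {
    ncon <- file(nodes_path, open = "wb")
    writeLines(c("id\tkind\tde_status",
                 sprintf("%s\t%s\t%s", net$nodes$id, net$nodes$kind,
                         net$nodes$de_status)),
               ncon, useBytes = TRUE)
    close(ncon)
  }
  invisible(path)
}

#' Read an expression table
#'
#' Expects a TSV with header columns `gene_id`, `fold_change`, `p_value`
#' (extra columns ignored). Rows with non-numeric fold change or p-value are
#' dropped with a warning naming the line numbers; p-values outside [0, 1]
#' or non-positive fold changes are invariant violations and raise an error.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene_id` (character), `fold_change`
#'   and `p_value` (numeric), one row per retained record.
#' @export
read_expression_table <- function(path) {
  lines <- .read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty expression table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_id", "fold_change", "p_value")
  if (!all(need %in% header))
    stop("expression table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  lineno <- lineno[-1]
  get <- function(col) vapply(cells, function(x) {
    i <- match(col, header)
    if (i <= length(x)) x[i] else NA_character_
  }, "")
  gene <- get("gene_id")
  fc <- suppressWarnings(as.numeric(get("fold_change")))
  p <- suppressWarnings(as.numeric(get("p_value")))
  bad <- is.na(fc) | is.na(p) | is.na(gene) | !nzchar(gene)
  if (any(bad)) {
    warning("rejected ", sum(bad), " non-numeric/incomplete row(s) at line(s) ",
            paste(lineno[bad], collapse = ", "), call. = FALSE)
    gene <- gene[!bad]; fc <- fc[!bad]; p <- p[!bad]
  }
  if (any(p < 0 | p > 1))
    stop("p_value outside [0, 1] at line(s) ",
         paste(lineno[!bad][p < 0 | p > 1], collapse = ", "), call. = FALSE)
  if (any(fc <= 0))
    stop("fold_change must be > 0 at line(s) ",
         paste(lineno[!bad][fc <= 0], collapse = ", "), call. = FALSE)
  data.frame(gene_id = gene, fold_change = fc, p_value = p,
             stringsAsFactors = FALSE)
}

#' Write an expression table
#'
#' @param records Data frame with `gene_id`, `fold_change`, `p_value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene_id\tfold_change\tp_value",
               sprintf("%s\t%.17g\t%.17g", records$gene_id,
                       records$fold_change, records$p_value)),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT annotation set
#'
#' GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`. The
#' background universe defaults to the union of all annotated genes; an
#' explicit background must cover every annotated gene. Terms with zero
#' genes and duplicate term ids are load errors.
#'
#' @param path Path to the GMT file.
#' @param background Optional character vector: explicit background universe.
#' @return An object of class `annotation_set`: a list with `terms` (named
#'   list of `list(description, genes)`) and `background`.
#' @export
read_annotations <- function(path, background = NULL) {
  lines <- .read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(cells) < 3
  if (any(short))
    stop("GMT term with zero genes: ",
         vapply(cells[short], `[`, "", 1)[1], call. = FALSE)
  ids <- vapply(cells, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  terms <- lapply(cells, function(x)
    list(description = x[2], genes = unique(x[-(1:2)])))
  names(terms) <- ids
  annotation_set(terms, background)
}

#' Construct a validated annotation set
#'
#' @param terms Named list; each element `list(description, genes)`.
#' @param background Optional explicit background universe (character).
#'   Defaults to the union of all annotated genes.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(terms, background = NULL) {
  if (!length(terms) || is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("terms must be a non-empty named list", call. = FALSE)
  if (any(vapply(terms, function(t) length(t$genes) == 0, TRUE)))
    stop("empty annotation term(s) not allowed", call. = FALSE)
  all_genes <- unique(unlist(lapply(terms, `[[`, "genes"), use.names = FALSE))
  if (is.null(background)) {
    background <- all_genes
  } else {
    background <- unique(as.character(background))
    missing <- setdiff(all_genes, background)
    if (length(missing))
      stop("annotated gene(s) missing from background: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...", call. = FALSE)
  }
  structure(list(terms = terms, background = sort(background)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  sizes <- lengths(lapply(x$terms, `[[`, "genes"))
  cat("Annotation set:", length(x$terms), "terms,",
      length(x$background), "background genes\n")
  cat("  term sizes: min", min(sizes), "median", stats::median(sizes),
      "max", max(sizes), "\n")
  invisible(x)
}

#' Write a GMT annotation set
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- vapply(names(ann$terms), function(id) {
    t <- ann$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a ranked hub-score table
#'
#' Emits the `rank, node, method, score` TSV used for top-k hub reports.
#'
#' @param table A [hub_score_table] (see [bn_scores()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hub_table <- function(table, path) {
  stopifnot(inherits(table, "hub_score_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("rank\tnode\tmethod\tscore",
               sprintf("%d\t%s\t%s\t%.17g", table$rank, table$node,
                       attr(table, "method"), table$score)),
             con, useBytes = TRUE)
  invisible(path)
}
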