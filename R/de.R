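# Differential-expression screening: threshold rules producing the up/down
# gene sets that seed network construction and subtraction.

#' Construct a DE gene set
#'
#' Holds disjoint up- and downregulated gene id sets together with the
#' thresholds that produced them.
#'
#' @param up,down Character vectors of gene ids.
#' @param thresholds Named list `list(up_fc, down_fc, alpha)` recording the
#'   screen exactly as applied.
#' @return An object of class `de_gene_set`.
#' @export
de_gene_set <- function(up = character(), down = character(),
                        thresholds = list(up_fc = NA_real_,
                                          down_fc = NA_real_,
                                          alpha = NA_real_)) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  clash <- intersect(up, down)
  if (length(clash))
    stop("gene(s) in both directions: ", paste(clash, collapse = ", "),
         call. = FALSE)
  structure(list(up = up, down = down, thresholds = thresholds),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  th <- x$thresholds
  cat("DE gene set:", length(x$up), "up,", length(x$down), "down\n")
  cat(sprintf("  screen: FC > %s (up), FC < %s (down), p < %s\n",
              format(th$up_fc), format(th$down_fc), format(th$alpha)))
  invisible(x)
}

#' Select differentially expressed genes by threshold screening
#'
#' Applies the fold-change/p-value screen: a gene is upregulated when its
#' fold change is strictly greater than `up_fc` and its p-value strictly
#' less than `alpha`; downregulated when fold change is strictly less than
#' `down_fc` with the same p-value condition. Records at exactly a
#' threshold are never selected. P-values are used raw — the screen applies
#' no multiple-testing correction. When a gene id appears more than once,
#' the record with the smallest p-value wins (most-significant evidence);
#' duplicate ids with conflicting values at the same minimal p-value are an
#' input error.
#'
#' @param records Data frame with `gene_id`, `fold_change`, `p_value`
#'   (as from [read_expression_table()]).
#' @param up_fc Upregulation fold-change threshold (default 1.5).
#' @param down_fc Downregulation fold-change threshold (default 0.66).
#' @param alpha P-value threshold (default 0.05).
#' @return A [de_gene_set()] with the thresholds recorded.
#' @examples
#' rec <- data.frame(gene_id = c("A", "B", "C", "D"),
#'                   fold_change = c(2.0, 0.5, 2.0, 1.2),
#'                   p_value = c(0.01, 0.01, 0.2, 0.001))
#' select_de_genes(rec)
#' @export
select_de_genes <- function(records, up_fc = 1.5, down_fc = 0.66,
                            alpha = 0.05) {
  stopifnot(nrow(records) > 0, up_fc > down_fc, down_fc > 0,
            alpha > 0, alpha < 1)
  if (anyDuplicated(records$gene_id)) {
    by_gene <- split(records, records$gene_id)
    # minimal p wins; distinct fold changes at the same minimal p are
    # ambiguous and rejected rather than silently resolved
    conflicted <- names(by_gene)[vapply(by_gene, function(r) {
      at_min <- r[r$p_value == min(r$p_value), , drop = FALSE]
      length(unique(at_min$fold_change)) > 1
    }, TRUE)]
    if (length(conflicted))
      stop("conflicting duplicate record(s) for gene(s): ",
           paste(conflicted, collapse = ", "), call. = FALSE)
    records <- do.call(rbind, lapply(by_gene, function(r)
      r[which.min(r$p_value), , drop = FALSE]))
  }
  sig <- records$p_value < alpha
  up <- records$gene_id[sig & records$fold_change > up_fc]
  down <- records$gene_id[sig & records$fold_change < down_fc]
  de_gene_set(up, down,
              thresholds = list(up_fc = up_fc, down_fc = down_fc,
                                alpha = alpha))
}

#' Merge curated gene calls into a DE gene set
#'
#' Adds externally validated genes (e.g. confirmed by real-time PCR) to the
#' screened sets, direction by direction. A merge that would place a gene in
#' both directions is a conflict error.
#'
#' @param deset A [de_gene_set()].
#' @param extra_up,extra_down Character vectors of gene ids to add.
#' @return The merged [de_gene_set()] (thresholds unchanged).
#' @export
merge_curated_genes <- function(deset, extra_up = character(),
                                extra_down = character()) {
  stopifnot(inherits(deset, "de_gene_set"))
  up <- union(deset$up, as.character(extra_up))
  down <- union(deset$down, as.character(extra_down))
  clash <- intersect(up, down)
  if (length(clash))
    stop("merge places gene(s) in both directions: ",
         paste(clash, collapse = ", "), call. = FALSE)
  de_gene_set(up, down, thresholds = deset$thresholds)
}

#' All differentially expressed gene ids
#'
#' @param deset A [de_gene_set()].
#' @return Character vector `union(up, down)`.
#' @export
de_genes <- function(deset) {
  stopifnot(inherits(deset, "de_gene_set"))
  sort(union(deset$up, deset$down))
}
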