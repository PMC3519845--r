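# Over-representation analysis: upper-tail hypergeometric (Fisher) test of
# annotation-term membership in a study gene set, with multiple-testing
# correction.

#' Hypergeometric over-representation analysis
#'
#' For each annotation term with at least one study gene, computes the
#' upper-tail hypergeometric probability \eqn{P(X \ge k)} of drawing
#' \eqn{k} annotated genes in a study sample of size \eqn{n} from a
#' background of \eqn{N} genes of which \eqn{K} carry the term — the
#' one-sided Fisher exact test for over-representation. Study genes outside
#' the background are dropped (with a message reporting the count).
#' Adjusted p-values use Benjamini-Hochberg by default (Bonferroni
#' available) across all tested terms.
#'
#' @param study Character vector of study gene ids.
#' @param ann An [annotation_set()].
#' @param correction `"bh"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @return A data frame of class `enrichment_result` with columns
#'   `term_id`, `description`, `k` (study genes with the term), `K`
#'   (background genes with the term), `n` (effective study size), `N`
#'   (background size), `p_raw`, `p_adj`; sorted by `p_adj` then
#'   `term_id`. Terms with `k = 0` are excluded.
#' @examples
#' ann <- annotation_set(list(
#'   TA = list(description = "term A", genes = paste0("g", 1:5)),
#'   TB = list(description = "term B", genes = paste0("g", 4:12))),
#'   background = paste0("g", 1:20))
#' fisher_enrichment(paste0("g", 1:10), ann)
#' @export
fisher_enrichment <- function(study, ann, correction = c("bh", "bonferroni")) {
  stopifnot(inherits(ann, "annotation_set"))
  correction <- match.arg(correction)
  study <- unique(as.character(study))
  dropped <- sum(!(study %in% ann$background))
  if (dropped)
    message(dropped, " study gene(s) outside the background were dropped")
  study <- intersect(study, ann$background)
  if (!length(study))
    stop("no study genes in the background", call. = FALSE)
  N <- length(ann$background)
  n <- length(study)
  rows <- lapply(names(ann$terms), function(id) {
    genes <- intersect(ann$terms[[id]]$genes, ann$background)
    K <- length(genes)
    k <- length(intersect(genes, study))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = ann$terms[[id]]$description,
               k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_result", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw,
                               method = if (correction == "bh") "BH"
                                        else "bonferroni")
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Filter enrichment results by adjusted significance
#'
#' Keeps results with `p_adj` strictly below `alpha` (typical reporting
#' levels are 5e-5 and 0.05), preserving order.
#'
#' @param results An `enrichment_result` from [fisher_enrichment()].
#' @param alpha Significance level in (0, 1).
#' @return The filtered `enrichment_result`.
#' @export
filter_significant <- function(results, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  out <- results[results$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Write enrichment results as TSV
#'
#' Columns mirror the usual over-representation report: term, corrected
#' p-value, number of annotations in the study set, description.
#'
#' @param results An `enrichment_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("term_id\tp_adj\tp_raw\tk\tK\tn\tN\tdescription",
               sprintf("%s\t%.6g\t%.6g\t%d\t%d\t%d\t%d\t%s",
                       results$term_id, results$p_adj, results$p_raw,
                       results$k, results$K, results$n, results$N,
                       results$description)),
             con, useBytes = TRUE)
  invisible(path)
}
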