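#' Percentile-shift normalization
#'
#' Subtracts from each sample (column) its `q`-quantile, computed with the
#' linear-interpolation quantile definition (type 7), so that after the shift
#' every sample's `q`-quantile is exactly zero. With the default `q = 0.75`
#' this is the classic 75th-percentile normalization for one-colour arrays.
#'
#' @param expr Probes x samples numeric matrix of log2 intensities.
#' @param q Quantile to anchor at zero, in (0, 1).
#' @param type Quantile algorithm (see [stats::quantile()]); type 7 default.
#' @return Matrix of the same shape.
#' @export
percentile_shift <- function(expr, q = 0.75, type = 7) {
  stopifnot(is.matrix(expr), q > 0, q < 1)
  if (any(colSums(is.finite(expr)) == 0)) stop("sample column with no values")
  qs <- apply(expr, 2, stats::quantile, probs = q, type = type, names = FALSE)
  sweep(expr, 2, qs, "-")
}

#' Baseline transform to the per-probe median
#'
#' Subtracts from each probe (row) its median across all samples, producing
#' the zero-centred per-gene scale on which downstream cut-offs live. After
#' the transform every probe's median is exactly zero.
#'
#' @param expr Probes x samples numeric matrix.
#' @return Matrix of the same shape.
#' @export
baseline_median_transform <- function(expr) {
  stopifnot(is.matrix(expr))
  if (any(rowSums(is.finite(expr)) == 0)) stop("probe row with no values")
  expr - apply(expr, 1, stats::median)
}

#' Filter probes by expression range
#'
#' Removes any probe with at least one value strictly outside `[lo, hi]`
#' (outlier removal on the normalized scale). Retained values are untouched.
#'
#' @param expr Probes x samples numeric matrix.
#' @param lo,hi Range bounds (default -7 to 7).
#' @return List with `expr` (filtered matrix) and `report`, a
#'   `probe_filter_report` recording counts and removed probe IDs.
#' @export
filter_by_range <- function(expr, lo = -7.0, hi = 7.0) {
  stopifnot(is.matrix(expr), lo < hi)
  out <- rowSums(expr < lo | expr > hi, na.rm = TRUE) > 0
  report <- structure(list(n_before = nrow(expr), n_after = sum(!out),
                           removed_out_of_range = rownames(expr)[out],
                           removed_blacklist = character(0)),
                      class = "probe_filter_report")
  list(expr = expr[!out, , drop = FALSE], report = report)
}

#' Sex-chromosome-linked genes removed by default
#'
#' The six predominantly X/Y-linked genes dropped before differential
#' analysis so that the sex imbalance between arms cannot masquerade as a
#' disease signal.
#' @return Character vector of gene symbols.
#' @export
sex_linked_blacklist <- function() {
  c("DDX3Y", "PSPHP1", "XIST", "RPS4Y1", "RPS4Y2", "BTNL8")
}

#' Drop probes mapping to blacklisted genes
#'
#' @param expr Probes x samples numeric matrix.
#' @param probes data.frame with `probe_id` and `gene` columns mapping rows of
#'   `expr` to gene symbols; if `NULL`, row names are taken as gene symbols.
#' @param blacklist Genes to remove; defaults to [sex_linked_blacklist()].
#'   Absent genes are no-ops.
#' @return List with `expr`, `probes` (both filtered) and `report`.
#' @export
drop_probes <- function(expr, probes = NULL, blacklist = sex_linked_blacklist()) {
  stopifnot(is.matrix(expr))
  if (is.null(probes))
    probes <- data.frame(probe_id = rownames(expr), gene = rownames(expr),
                         stringsAsFactors = FALSE)
  probes <- probes[match(rownames(expr), probes$probe_id), , drop = FALSE]
  out <- probes$gene %in% blacklist
  report <- structure(list(n_before = nrow(expr), n_after = sum(!out),
                           removed_out_of_range = character(0),
                           removed_blacklist = rownames(expr)[out]),
                      class = "probe_filter_report")
  list(expr = expr[!out, , drop = FALSE],
       probes = probes[!out, , drop = FALSE], report = report)
}

#' @export
print.probe_filter_report <- function(x, ...) {
  cat(sprintf("Probe filter: %d -> %d (%d out of range, %d blacklisted)\n",
              x$n_before, x$n_after,
              length(x$removed_out_of_range), length(x$removed_blacklist)))
  invisible(x)
}

#' Full normalization and filtering pipeline
#'
#' Runs, in order: percentile shift (75th percentile), per-probe median
#' baseline transform, expression-range filter (-7..7), sex-linked blacklist
#' removal. Downstream statistics assume the resulting per-probe
#' median-centred scale.
#'
#' @param cohort A `sep_cohort` (or any list with `expr` and `probes`).
#' @param q Anchoring quantile for the percentile shift.
#' @param lo,hi Expression-range filter bounds.
#' @param blacklist Genes to drop.
#' @return The cohort with normalized, filtered `expr`/`probes` plus a
#'   `filter_report` entry combining both removal lists.
#' @export
preprocess_cohort <- function(cohort, q = 0.75, lo = -7.0, hi = 7.0,
                              blacklist = sex_linked_blacklist()) {
  expr <- baseline_median_transform(percentile_shift(cohort$expr, q = q))
  f1 <- filter_by_range(expr, lo = lo, hi = hi)
  f2 <- drop_probes(f1$expr, cohort$probes, blacklist)
  report <- structure(list(n_before = nrow(cohort$expr), n_after = nrow(f2$expr),
                           removed_out_of_range = f1$report$removed_out_of_range,
                           removed_blacklist = f2$report$removed_blacklist),
                      class = "probe_filter_report")
  cohort$expr <- f2$expr
  cohort$probes <- f2$probes
  cohort$filter_report <- report
  cohort
}
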