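#' Signed linear fold change between two groups of log2 values
#'
#' With `d = mean(a) - mean(b)` on the log2 scale, returns `+2^d` when
#' `d >= 0` and `-2^(-d)` otherwise, so `|FC| >= 1` always and down-regulation
#' carries a negative sign (the convention of microarray result tables).
#'
#' @param a,b Numeric vectors of log2 expression (non-empty).
#' @return Signed linear fold change.
#' @examples
#' fold_change(c(5, 5), c(0, 0))  # +32
#' fold_change(c(0, 0), c(2, 2))  # -4
#' @export
fold_change <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  d <- mean(a) - mean(b)
  if (d >= 0) 2^d else -2^(-d)
}

#' Two-sample t-test
#'
#' Welch (Satterthwaite degrees of freedom) by default; pooled-variance by
#' flag. When both groups have zero variance and equal means the test is
#' degenerate and `p = 1` by convention.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance test (default) or pooled.
#' @return Named list `t`, `p` (two-sided).
#' @export
t_test <- function(a, b, welch = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F ratio with p from the F distribution.
#' Degenerate conventions: all values identical gives `F = 0, p = 1`; zero
#' within-group variance with distinct group means gives `F = Inf, p = 0`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return Named list `f`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  v <- unlist(groups, use.names = FALSE)
  if (all(v == v[1])) return(list(f = 0, p = 1))
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within == 0) return(list(f = Inf, p = 0))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(f = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-aligned with the input and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration when the combined sample size is at most
#' `exact_max` and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections. `U` counts pairs where `a` exceeds `b`
#' (ties half-counted).
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact_max Combined-n threshold for the exact branch.
#' @return Named list `u`, `p`.
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' PCA sample scores
#'
#' Scores from the eigendecomposition of the sample covariance of
#' probe-centred data. Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param expr Probes x samples numeric matrix.
#' @param k Number of components (at most the matrix rank).
#' @return List with `scores` (samples x k), `sdev` (component SDs) and
#'   `loadings` (probes x k).
#' @export
pca_scores <- function(expr, k = 2) {
  stopifnot(is.matrix(expr), k >= 1)
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) stop("k exceeds matrix rank (", rank, ")")
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  list(scores = sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*"),
       sdev = pc$sdev[seq_len(k)],
       loadings = sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*"))
}

## Vectorised one-way ANOVA F and p across all probes of a matrix.
## Same statistic as one_way_anova(), computed with group-mean algebra so
## array-wide screens stay fast.
anova_by_probe <- function(expr, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- ncol(expr)
  stopifnot(k >= 2, n == length(group))
  G <- stats::model.matrix(~ 0 + group)           # n x k indicator
  ng <- colSums(G)
  gm <- sweep(expr %*% G, 2, ng, "/")             # probe x k group means
  grand <- rowMeans(expr)
  ssb <- as.vector(gm^2 %*% ng) - n * grand^2
  sst <- rowSums(expr^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb > 1e-12] <- 0
  f[ssw == 0 & ssb > 1e-12] <- Inf
  data.frame(probe_id = rownames(expr), f = f, p = p,
             stringsAsFactors = FALSE)
}

#' Differential-expression table for one comparison
#'
#' Per-probe signed fold change, t-test (Welch), raw and BH-adjusted p over a
#' two-group comparison at one timepoint — the "volcano table" consumed by
#' panel selection.
#'
#' @param cohort A (preprocessed) `sep_cohort`.
#' @param groups_a,groups_b Group labels forming the two sides.
#' @param timepoint Timepoint label, or `NULL` for all timepoints combined.
#' @param welch Welch t-test flag, see [t_test()].
#' @return data.frame: probe_id, gene, fc, log2fc, t, p, q.
#' @export
diff_table <- function(cohort, groups_a, groups_b, timepoint = "D1",
                       welch = TRUE) {
  ann <- cohort$annotation
  sel <- if (is.null(timepoint)) rep(TRUE, nrow(ann)) else ann$timepoint == timepoint
  ia <- ann$sample_id[sel & ann$group %in% groups_a]
  ib <- ann$sample_id[sel & ann$group %in% groups_b]
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 samples per side")
  A <- cohort$expr[, ia, drop = FALSE]
  B <- cohort$expr[, ib, drop = FALSE]
  d <- rowMeans(A) - rowMeans(B)
  stat <- vapply(seq_len(nrow(A)), function(i) {
    tt <- t_test(A[i, ], B[i, ], welch = welch)
    c(tt$t, tt$p)
  }, c(0, 0))
  out <- data.frame(probe_id = rownames(A),
                    gene = cohort$probes$gene[match(rownames(A), cohort$probes$probe_id)],
                    fc = ifelse(d >= 0, 2^d, -2^(-d)), log2fc = d,
                    t = stat[1, ], p = stat[2, ], stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out
}
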