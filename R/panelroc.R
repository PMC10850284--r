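#' Signed additive panel definition
#'
#' A biomarker panel is an ordered list of genes each carrying a sign: the
#' composite score of a sample is the signed sum of the genes' normalized
#' expression values (+ for genes up-regulated in the positive class, - for
#' down-regulated ones).
#'
#' @param spec Either a formula-like string `"GENE1+GENE2-GENE3"` (a leading
#'   `+` is implied) or a character vector of genes used with `signs`.
#' @param signs Numeric vector of +1/-1, recycled; ignored when `spec` is a
#'   single signature string.
#' @param name Panel name (defaults to the canonical signature string).
#' @param probe_policy How to collapse multiple probes of one gene:
#'   `"best_auc"` (pick the probe with the highest single-probe AUC for the
#'   comparison at hand), `"mean"` (average probes), or `"first"`.
#' @return Object of class `panel_def` with `terms` (data.frame gene, sign).
#' @examples
#' panel_def("CETP+CMTM5+MIA-MPP3-PLA2G7")
#' @export
panel_def <- function(spec, signs = 1, name = NULL,
                      probe_policy = c("best_auc", "mean", "first")) {
  probe_policy <- match.arg(probe_policy)
  if (length(spec) == 1 && grepl("[+-]", substring(spec, 2))) {
    s <- gsub("\\s", "", spec)
    if (!grepl("^[+-]", s)) s <- paste0("+", s)
    genes <- strsplit(s, "[+-]")[[1]][-1]
    signs <- ifelse(strsplit(gsub("[^+-]", "", s), "")[[1]] == "+", 1, -1)
  } else {
    genes <- as.character(spec)
    signs <- rep_len(signs, length(genes))
  }
  if (!length(genes)) stop("panel needs at least one term")
  if (anyDuplicated(genes)) stop("duplicate genes in panel")
  stopifnot(all(signs %in% c(-1, 1)))
  canonical <- paste0(ifelse(signs > 0, "+", "-"), genes, collapse = "")
  structure(list(name = if (is.null(name)) sub("^\\+", "", canonical) else name,
                 terms = data.frame(gene = genes, sign = signs,
                                    stringsAsFactors = FALSE),
                 probe_policy = probe_policy),
            class = "panel_def")
}

#' @export
print.panel_def <- function(x, ...) {
  cat(sprintf("Panel '%s' (%d terms, probe policy %s)\n", x$name,
              nrow(x$terms), x$probe_policy))
  invisible(x)
}

#' Preset biomarker panels
#'
#' The shipped catalogue of signed additive signatures: the
#' indicators-of-inflammation (IoI) combinations separating severe
#' inflammation from healthy controls, the SIRS-or-sepsis (SoS)
#' discriminator combinations, and the published SeptiCyte Lab signature
#' (PLAC8 - PLA2G7 + LAMP1 - CEACAM4) as an external comparator. The SoS
#' 5-gene signature is also provided in a variant with MIA negated, matching
#' an alternative printed orientation of that panel.
#'
#' @param name Optional preset name; omit to list the whole catalogue.
#' @return A `panel_def`, or a data.frame cataloguing all presets.
#' @export
panel_presets <- function(name = NULL) {
  cat <- utils::read.delim(system.file("extdata", "panel_presets.tsv",
                                       package = "sepsig"),
                           stringsAsFactors = FALSE)
  if (is.null(name)) return(cat)
  row <- cat[cat$name == name, ]
  if (!nrow(row)) stop("unknown preset: ", name, "; see panel_presets()")
  panel_def(row$signature, name = row$name)
}

## Collapse a panel's genes to one score row each, honouring probe_policy.
## Returns genes x samples matrix; errors on unresolvable genes unless
## `partial`, in which case missing genes are reported via attribute.
collapse_probes <- function(panel, expr, probes, labels = NULL, partial = FALSE) {
  gene_of <- probes$gene[match(rownames(expr), probes$probe_id)]
  rows <- lapply(panel$terms$gene, function(g) which(gene_of == g))
  missing <- panel$terms$gene[lengths(rows) == 0]
  if (length(missing) && !partial)
    stop("panel gene(s) not in matrix: ", paste(missing, collapse = ", "))
  keep <- lengths(rows) > 0
  out <- t(vapply(which(keep), function(i) {
    r <- rows[[i]]
    if (length(r) == 1) return(expr[r, ])
    switch(panel$probe_policy,
           mean = colMeans(expr[r, , drop = FALSE]),
           first = expr[r[1], ],
           best_auc = {
             if (is.null(labels))
               colMeans(expr[r, , drop = FALSE])
             else {
               aucs <- vapply(r, function(ri) {
                 a <- roc_auc(expr[ri, ] * panel$terms$sign[i], labels)$auc
                 a
               }, 0)
               expr[r[which.max(aucs)], ]
             }
           })
  }, numeric(ncol(expr))))
  rownames(out) <- panel$terms$gene[keep]
  attr(out, "missing") <- missing
  attr(out, "signs") <- panel$terms$sign[keep]
  out
}

#' Composite panel score
#'
#' Per-sample signed sum of the panel genes' values: linear in the data, so
#' adding a constant to one +1 gene shifts every score by that constant.
#'
#' @param panel A [panel_def()].
#' @param expr Probes x samples numeric matrix (normalized scale).
#' @param probes Optional data.frame (probe_id, gene) mapping rows to genes;
#'   defaults to row names as gene symbols.
#' @param labels Optional 0/1 labels used only by the `best_auc` probe
#'   collapse policy.
#' @return Named numeric vector of per-sample scores.
#' @export
composite_score <- function(panel, expr, probes = NULL, labels = NULL) {
  stopifnot(inherits(panel, "panel_def"), is.matrix(expr))
  if (is.null(probes))
    probes <- data.frame(probe_id = rownames(expr), gene = rownames(expr),
                         stringsAsFactors = FALSE)
  g <- collapse_probes(panel, expr, probes, labels)
  as.numeric(crossprod(g, attr(g, "signs")))[seq_len(ncol(expr))] |>
    stats::setNames(colnames(expr))
}

#' ROC curve with AUC and Hanley-McNeil standard error
#'
#' The AUC is the pair-counting statistic (probability that a random
#' positive outscores a random negative, ties half-counted), identical to
#' the trapezoidal area of the curve traced over all midpoint thresholds.
#' The standard error is Hanley-McNeil with `Q1 = A/(2-A)`,
#' `Q2 = 2A^2/(1+A)`.
#'
#' @param scores Numeric scores, oriented positive-class-high.
#' @param labels 0/1 (or logical, or 2-level factor) class labels.
#' @return Object of class `roc_curve`: `thresholds` (midpoints between
#'   consecutive distinct scores with -Inf/+Inf ends), `sensitivity`,
#'   `specificity` per threshold, `auc`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores <= t & labels == 0) / n_neg, 0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, se = se, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) stop("labels must be binary")
    return(as.integer(labels) - 1L)
  }
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop("labels must be 0/1, logical, or 2-level factor")
  as.integer(labels)
}

#' @export
print.roc_curve <- function(x, ...) {
  ci <- auc_ci(x$auc, x$se, 0.90)
  cat(sprintf("ROC: AUC %.4f (SE %.5f, 90%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, x$se, ci[1], ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.4f", x$auc))
  invisible(x)
}

#' Normal-theory confidence interval for an AUC
#'
#' `auc +/- z(level) * se`, clipped to `[0, 1]`; `z(0.90) = 1.6449`. Takes
#' the AUC and SE explicitly so printed values can be fed in directly.
#'
#' @param auc AUC in `[0, 1]`.
#' @param se Standard error (>= 0).
#' @param level Two-sided confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
auc_ci <- function(auc, se, level = 0.90) {
  stopifnot(auc >= 0, auc <= 1, se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  pmin(1, pmax(0, c(auc - z * se, auc + z * se)))
}

#' Likelihood ratios from percent sensitivity/specificity
#'
#' `LR+ = sens / (100 - spec)`, `LR- = (100 - sens) / spec`, on the percent
#' scale of diagnostic result tables. Zero denominators give `Inf` (a defined
#' return, not an error).
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`.
#' @return Named numeric `c(lr_pos, lr_neg)`.
#' @examples
#' likelihood_ratios(98.80, 96.67)  # LR+ 29.67
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  lr_pos <- if (specificity == 100) Inf else sensitivity / (100 - specificity)
  lr_neg <- if (specificity == 0) Inf else (100 - sensitivity) / specificity
  c(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Accuracy-optimal score cut-off
#'
#' Scans every midpoint threshold (and the open ends) and returns the one
#' maximising classification accuracy `(tp + tn) / n`; ties are broken by
#' maximal Youden J (sens + spec - 1), then by the smallest threshold.
#' Prediction rule: positive iff `score > cutoff`.
#'
#' @param scores,labels As in [roc_auc()].
#' @return The cut-off value.
#' @export
best_cutoff <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  rc <- roc_auc(scores, labels)
  acc <- (rc$sensitivity * rc$n_pos + rc$specificity * rc$n_neg) /
    (rc$n_pos + rc$n_neg)
  youden <- rc$sensitivity + rc$specificity - 1
  cand <- which(acc == max(acc))
  cand <- cand[youden[cand] == max(youden[cand])]
  rc$thresholds[cand[1]]  # thresholds ascending: first = smallest
}

#' Diagnostic metrics at a cut-off
#'
#' Confusion counts under "positive iff score > cutoff", with sensitivity,
#' specificity, PPV, NPV (Clopper-Pearson exact 95% CIs) and likelihood
#' ratios. An empty predicted class makes the corresponding predictive value
#' `NaN`, flagged in `undefined`.
#'
#' @param scores,labels As in [roc_auc()].
#' @param cutoff Score threshold.
#' @param conf_level Confidence level for the proportion CIs.
#' @return Object of class `diag_metrics`.
#' @export
diagnostics_at <- function(scores, labels, cutoff, conf_level = 0.95) {
  labels <- as_binary_labels(labels)
  pred <- scores > cutoff
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  prop <- function(num, den) if (den == 0) NaN else num / den
  ci <- function(num, den) {
    if (den == 0) return(c(NaN, NaN))
    as.numeric(stats::binom.test(num, den, conf.level = conf_level)$conf.int)
  }
  sens <- prop(tp, tp + fn); spec <- prop(tn, tn + fp)
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn),
                 sensitivity_ci = ci(tp, tp + fn),
                 specificity_ci = ci(tn, tn + fp),
                 ppv_ci = ci(tp, tp + fp), npv_ci = ci(tn, tn + fn),
                 lr_pos = if (!is.nan(spec) && spec == 1) Inf else sens / (1 - spec),
                 lr_neg = if (!is.nan(spec) && spec == 0) Inf else (1 - sens) / spec,
                 undefined = c(ppv = (tp + fp) == 0, npv = (tn + fn) == 0),
                 conf_level = conf_level),
            class = "diag_metrics")
}

#' @export
print.diag_metrics <- function(x, ...) {
  pct <- function(v) if (is.nan(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("Cut-off > %.4g: tp %d fp %d tn %d fn %d\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sens %s  spec %s  PPV %s  NPV %s  LR+ %.2f  LR- %.2f\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
              x$lr_pos, x$lr_neg))
  invisible(x)
}

#' Cut-off achieving a target predictive value
#'
#' Scans all midpoint thresholds; among those whose PPV (or NPV) meets the
#' target, returns the one maximising the complementary yield — sensitivity
#' for a PPV target (rule-in use), specificity for an NPV target (rule-out
#' use). Returns `NA` when the target is unattainable.
#'
#' @param scores,labels As in [roc_auc()].
#' @param metric `"ppv"` or `"npv"`.
#' @param target Target predictive value as a fraction in (0, 1).
#' @return The cut-off, or `NA_real_` if no threshold qualifies.
#' @export
threshold_for_target <- function(scores, labels, metric = c("ppv", "npv"),
                                 target) {
  metric <- match.arg(metric)
  stopifnot(target > 0, target < 1)
  labels <- as_binary_labels(labels)
  rc <- roc_auc(scores, labels)
  stats_at <- vapply(rc$thresholds, function(t) {
    d <- diagnostics_at(scores, labels, t)
    c(ppv = d$ppv, npv = d$npv, sens = d$sensitivity, spec = d$specificity)
  }, c(0, 0, 0, 0))
  value <- stats_at[metric, ]
  yield <- stats_at[if (metric == "ppv") "sens" else "spec", ]
  ok <- !is.nan(value) & value >= target
  if (!any(ok)) return(NA_real_)
  cand <- which(ok)
  rc$thresholds[cand[which.max(yield[cand])]]
}

#' Evaluate a panel on an expression cohort
#'
#' Computes composite scores for a positive-vs-negative group comparison and
#' returns the full report: ROC curve, diagnostics at the accuracy-optimal
#' cut-off, and at the cut-offs targeting a rule-in PPV and a rule-out NPV
#' (with the indeterminate zone between them). Genes absent from the matrix
#' abort the evaluation for the panel — they are reported, never silently
#' imputed.
#'
#' @param panel A [panel_def()].
#' @param cohort A `sep_cohort` (normalized).
#' @param positive,negative Character vectors of group labels on each side.
#' @param timepoint Timepoint label, or `NULL` for all.
#' @param ppv_target,npv_target Rule-in / rule-out predictive-value targets.
#' @return Object of class `panel_eval`; if genes are missing, a
#'   `panel_eval_missing` stub listing them (no AUC emitted).
#' @export
evaluate_panel <- function(panel, cohort, positive, negative,
                           timepoint = "D1", ppv_target = 0.95,
                           npv_target = 0.98) {
  stopifnot(inherits(panel, "panel_def"))
  ann <- cohort$annotation
  sel <- if (is.null(timepoint)) rep(TRUE, nrow(ann)) else ann$timepoint == timepoint
  pos_ids <- ann$sample_id[sel & ann$group %in% positive]
  neg_ids <- ann$sample_id[sel & ann$group %in% negative]
  if (!length(pos_ids) || !length(neg_ids)) stop("empty comparison group")
  gene_of <- cohort$probes$gene[match(rownames(cohort$expr), cohort$probes$probe_id)]
  missing <- setdiff(panel$terms$gene, gene_of)
  if (length(missing))
    return(structure(list(panel = panel, missing_genes = missing),
                     class = c("panel_eval_missing", "panel_eval")))
  ids <- c(pos_ids, neg_ids)
  labels <- rep(c(1L, 0L), c(length(pos_ids), length(neg_ids)))
  scores <- composite_score(panel, cohort$expr[, ids, drop = FALSE],
                            cohort$probes, labels = labels)
  roc <- roc_auc(scores, labels)
  cut_best <- best_cutoff(scores, labels)
  cut_ppv <- threshold_for_target(scores, labels, "ppv", ppv_target)
  cut_npv <- threshold_for_target(scores, labels, "npv", npv_target)
  structure(list(panel = panel, roc = roc, scores = scores, labels = labels,
                 missing_genes = character(0),
                 best = diagnostics_at(scores, labels, cut_best),
                 rule_in = if (!is.na(cut_ppv)) diagnostics_at(scores, labels, cut_ppv),
                 rule_out = if (!is.na(cut_npv)) diagnostics_at(scores, labels, cut_npv),
                 indeterminate_zone = if (!is.na(cut_ppv) && !is.na(cut_npv))
                   sort(c(cut_npv, cut_ppv)) else c(NA_real_, NA_real_),
                 positive = positive, negative = negative,
                 timepoint = timepoint),
            class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  if (inherits(x, "panel_eval_missing")) {
    cat(sprintf("Panel '%s': NOT evaluated; missing gene(s): %s\n",
                x$panel$name, paste(x$missing_genes, collapse = ", ")))
    return(invisible(x))
  }
  cat(sprintf("Panel '%s' (%s vs %s, %s)\n", x$panel$name,
              paste(x$positive, collapse = "/"),
              paste(x$negative, collapse = "/"),
              if (is.null(x$timepoint)) "all timepoints" else x$timepoint))
  print(x$roc)
  cat("At accuracy-optimal cut-off:\n"); print(x$best)
  if (!is.null(x$rule_in)) { cat("Rule-in cut-off:\n"); print(x$rule_in) }
  if (!is.null(x$rule_out)) { cat("Rule-out cut-off:\n"); print(x$rule_out) }
  invisible(x)
}

#' @export
plot.panel_eval <- function(x, ...) {
  if (inherits(x, "panel_eval_missing")) stop("panel was not evaluated")
  graphics::plot(x$roc, main = x$panel$name, ...)
}

#' Pairwise Spearman correlation of markers
#'
#' Rank correlations (mid-rank ties) between the expression of chosen genes,
#' optionally alongside a clinical covariate vector (e.g. CRP). Constant
#' vectors give `NA` correlations.
#'
#' @param cohort A `sep_cohort`.
#' @param genes Gene symbols to correlate (probes collapsed by mean).
#' @param extra Optional named list of clinical vectors aligned to the
#'   selected samples.
#' @param timepoint Timepoint label, or `NULL` for all.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlate_markers <- function(cohort, genes, extra = NULL, timepoint = "D1") {
  ann <- cohort$annotation
  sel <- if (is.null(timepoint)) rep(TRUE, nrow(ann)) else ann$timepoint == timepoint
  ids <- ann$sample_id[sel]
  gene_of <- cohort$probes$gene[match(rownames(cohort$expr), cohort$probes$probe_id)]
  vecs <- lapply(genes, function(g) {
    r <- which(gene_of == g)
    if (!length(r)) stop("gene not in cohort: ", g)
    colMeans(cohort$expr[r, ids, drop = FALSE])
  })
  names(vecs) <- genes
  if (!is.null(extra)) vecs <- c(vecs, lapply(extra, function(v) v[seq_along(ids)]))
  if (length(vecs) < 2) stop("need at least two vectors")
  m <- do.call(cbind, vecs)
  suppressWarnings(stats::cor(m, method = "spearman"))
}
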