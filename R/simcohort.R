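#' Cohort design for synthetic sepsis/SIRS expression studies
#'
#' Describes the sampling frame of a simulated ICU transcriptomics cohort:
#' group sizes at admission, the ordered series of sampling timepoints,
#' array size, noise level, per-timepoint dropout and per-group survival.
#' Defaults mirror a four-arm design with 30 healthy controls (CNTRL),
#' 42 SIRS (out-of-hospital cardiac arrest), 59 abdominal (ABDM) and 84
#' pulmonary (PLMN) sepsis patients sampled on Day 1, Day 2, Day 5 and at
#' discharge. Controls contribute Day-1 samples only.
#'
#' @param group_sizes Named integer vector of Day-1 sample counts per group.
#' @param timepoints Ordered character vector of timepoint labels.
#' @param n_probes Number of probes on the simulated array.
#' @param probe_noise_sd Per-measurement Gaussian noise SD, log2 units.
#' @param baseline_sd SD of per-probe baselines (drawn once, mean 0).
#' @param dropout_prob Probability that a surviving patient misses each
#'   post-Day-1 timepoint (missingness is monotone: once absent, absent at all
#'   later timepoints).
#' @param dropout_prob_dns Dropout probability for non-survivors; higher by
#'   default, so attrition is tied to outcome.
#' @param survival_prob Named vector of per-group survival probabilities.
#' @param probes_per_gene Number of probes emitted per planted gene (duplicate
#'   probes share the effect but get independent noise).
#' @param seed Integer seed; the same design + effects + seed reproduce the
#'   cohort bit-for-bit.
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()], [planted_effect()]
#' @export
cohort_design <- function(group_sizes = c(CNTRL = 30L, SIRS = 42L, ABDM = 59L, PLMN = 84L),
                          timepoints = c("D1", "D2", "D5", "DC"),
                          n_probes = 2000L,
                          probe_noise_sd = 0.5,
                          baseline_sd = 1.0,
                          dropout_prob = 0.10,
                          dropout_prob_dns = 0.25,
                          survival_prob = c(CNTRL = 1.0, SIRS = 0.6111,
                                            ABDM = 0.7451, PLMN = 0.7838),
                          probes_per_gene = 1L,
                          seed = 1L) {
  stopifnot(length(group_sizes) >= 1, !is.null(names(group_sizes)),
            all(group_sizes > 0), !anyDuplicated(timepoints),
            n_probes >= 1, probe_noise_sd >= 0, baseline_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            dropout_prob_dns >= 0, dropout_prob_dns <= 1,
            probes_per_gene >= 1)
  survival_prob <- survival_prob[names(group_sizes)]
  survival_prob[is.na(survival_prob)] <- 1.0
  names(survival_prob) <- names(group_sizes)
  if (any(survival_prob < 0 | survival_prob > 1))
    stop("survival probabilities must lie in [0, 1]")
  structure(list(group_sizes = as.integer(group_sizes) |> stats::setNames(names(group_sizes)),
                 timepoints = as.character(timepoints),
                 n_probes = as.integer(n_probes),
                 probe_noise_sd = probe_noise_sd,
                 baseline_sd = baseline_sd,
                 dropout_prob = dropout_prob,
                 dropout_prob_dns = dropout_prob_dns,
                 survival_prob = survival_prob,
                 probes_per_gene = as.integer(probes_per_gene),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Synthetic cohort design\n")
  cat("  groups:    ", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                             collapse = ", "), "\n")
  cat("  timepoints:", paste(x$timepoints, collapse = " > "), "\n")
  cat(sprintf("  probes: %d (x%d per planted gene), noise sd %.3g, seed %d\n",
              x$n_probes, x$probes_per_gene, x$probe_noise_sd, x$seed))
  invisible(x)
}

#' Planted differential-expression effect
#'
#' One gene's group-specific shift, expressed as a signed linear fold change
#' relative to unaffected groups. A fold change of +110.31 plants a
#' `log2(110.31)` upward shift in the affected groups; -7.09 plants a
#' `log2(7.09)` downward shift. The shift is scaled per timepoint by
#' `temporal_profile` (default declining towards discharge) and may carry an
#' extra log2 shift in non-survivors.
#'
#' @param gene Gene symbol.
#' @param affected_groups Character vector of group labels carrying the shift.
#' @param fold_change Signed linear fold change; `|fold_change| >= 1`.
#' @param temporal_profile Non-negative multiplier on the log2 shift per
#'   timepoint (recycled/truncated to the design's timepoints).
#' @param survival_modifier Extra log2 shift applied to non-survivors.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(gene, affected_groups, fold_change,
                           temporal_profile = c(1.0, 0.9, 0.6, 0.3),
                           survival_modifier = 0) {
  stopifnot(is.character(gene), length(gene) == 1,
            length(affected_groups) >= 1,
            abs(fold_change) >= 1, all(temporal_profile >= 0))
  structure(list(gene = gene, affected_groups = affected_groups,
                 fold_change = fold_change,
                 temporal_profile = temporal_profile,
                 survival_modifier = survival_modifier),
            class = "planted_effect")
}

#' Preset planted effects at indicator-of-inflammation scale
#'
#' Effects shared by SIRS and both sepsis groups versus healthy controls,
#' with Day-1 fold changes at the scale observed for strong inflammation
#' markers on one-colour arrays (up to ~110-fold for CD177).
#'
#' @return List of [planted_effect()] objects.
#' @export
ioi_effects <- function() {
  fc <- c(CD177 = 110.31, FAM20A = 55.35, MMP9 = 45.49, OLAH = 26.15,
          ITGA7 = 15.67, ADM = 12.95, TDRD9 = 14.53, IL10 = 7.06)
  lapply(names(fc), function(g)
    planted_effect(g, c("SIRS", "ABDM", "PLMN"), fc[[g]]))
}

#' Preset planted effects at SIRS-vs-sepsis discriminator scale
#'
#' Genes differentially expressed between SIRS and sepsis (~2-7-fold, both
#' signs). Up-regulated discriminators are planted in the sepsis groups;
#' down-regulated ones (i.e. higher in SIRS) are planted in the SIRS group,
#' so the signed sepsis-vs-SIRS fold change carries the stated sign.
#'
#' @return List of [planted_effect()] objects.
#' @export
sos_effects <- function() {
  up <- c(ITGB3 = 7.47, CETP = 4.95, CMTM5 = 4.93, PLXNB3 = 5.10, MIA = 3.20)
  dn <- c(PLA2G7 = 7.09, ARHGEF10L = 3.86, GPR124 = 3.34, MPP3 = 3.28)
  c(lapply(names(up), function(g) planted_effect(g, c("ABDM", "PLMN"), up[[g]])),
    lapply(names(dn), function(g) planted_effect(g, "SIRS", dn[[g]])))
}

#' Generate a synthetic expression cohort
#'
#' Draws a log2 expression matrix plus sample annotation under a
#' [cohort_design()]. Each entry is a per-probe baseline (drawn once, mean 0)
#' plus the planted group/timepoint effect shift (log2 of |fold change| times
#' the temporal multiplier, signed) plus independent Gaussian noise. Samples
#' are followed over timepoints with monotone attrition; non-survivors drop
#' out more. Controls are sampled at the first timepoint only.
#'
#' @param design A [cohort_design()].
#' @param effects List of [planted_effect()] objects (may be empty).
#' @return An object of class `sep_cohort`: a list with `expr` (probes x
#'   samples log2 matrix), `probes` (data.frame probe_id, gene), `annotation`
#'   (data.frame sample_id, subject_id, group, timepoint, survival) and the
#'   `design`/`effects` used.
#' @examples
#' co <- generate_cohort(cohort_design(n_probes = 50, seed = 7), ioi_effects()[1:2])
#' table(subset(co$annotation, timepoint == "D1")$group)
#' @export
generate_cohort <- function(design, effects = list()) {
  stopifnot(inherits(design, "cohort_design"))
  if (length(effects) && !all(vapply(effects, inherits, TRUE, "planted_effect")))
    stop("effects must be planted_effect objects")
  genes <- vapply(effects, `[[`, "", "gene")
  if (anyDuplicated(genes)) stop("duplicate planted genes")
  for (e in effects)
    if (!all(e$affected_groups %in% names(design$group_sizes)))
      stop("unknown group in planted effect for gene ", e$gene)
  n_effect_probes <- length(genes) * design$probes_per_gene
  if (design$n_probes < n_effect_probes)
    stop("n_probes smaller than the number of planted probes")

  local_seed(design$seed)

  ## probe table: planted genes first (k probes each), then background probes
  if (length(genes)) {
    probe_gene <- rep(genes, each = design$probes_per_gene)
    probe_id <- if (design$probes_per_gene > 1L)
      paste0(probe_gene, "_p", rep(seq_len(design$probes_per_gene), length(genes)))
    else probe_gene
  } else {
    probe_gene <- character(0); probe_id <- character(0)
  }
  n_bg <- design$n_probes - n_effect_probes
  if (n_bg > 0) {
    bg <- sprintf("BG%05d", seq_len(n_bg))
    probe_id <- c(probe_id, bg)
    probe_gene <- c(probe_gene, bg)
  }
  probes <- data.frame(probe_id = probe_id, gene = probe_gene,
                       stringsAsFactors = FALSE)

  ## subjects: survival and per-timepoint presence (monotone attrition)
  grp <- rep(names(design$group_sizes), design$group_sizes)
  subject_id <- sprintf("%s%03d", grp,
                        unlist(lapply(design$group_sizes, seq_len), use.names = FALSE))
  surv <- ifelse(stats::runif(length(grp)) < design$survival_prob[grp], "S", "DNS")
  tp <- design$timepoints
  present <- matrix(FALSE, length(grp), length(tp),
                    dimnames = list(subject_id, tp))
  present[, 1] <- TRUE
  ctrl_grp <- names(design$group_sizes)[1]
  for (j in seq_along(tp)[-1]) {
    pdrop <- ifelse(surv == "DNS", design$dropout_prob_dns, design$dropout_prob)
    keep <- present[, j - 1] & stats::runif(length(grp)) >= pdrop
    keep[grp == ctrl_grp] <- FALSE  # controls: admission sample only
    present[, j] <- keep
  }

  ann <- do.call(rbind, lapply(seq_along(tp), function(j) {
    idx <- which(present[, j])
    if (!length(idx)) return(NULL)
    data.frame(sample_id = paste0(subject_id[idx], "_", tp[j]),
               subject_id = subject_id[idx],
               group = grp[idx], timepoint = tp[j], survival = surv[idx],
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL

  ## expression: baseline + planted shifts + noise
  baseline <- stats::rnorm(design$n_probes, 0, design$baseline_sd)
  expr <- matrix(stats::rnorm(design$n_probes * nrow(ann), 0, design$probe_noise_sd),
                 design$n_probes, nrow(ann),
                 dimnames = list(probes$probe_id, ann$sample_id))
  expr <- expr + baseline
  tp_index <- match(ann$timepoint, tp)
  for (e in effects) {
    prof <- rep_len(e$temporal_profile, length(tp))
    shift0 <- sign(e$fold_change) * log2(abs(e$fold_change))
    rows <- which(probes$gene == e$gene)
    cols <- ann$group %in% e$affected_groups
    if (any(cols)) {
      add <- shift0 * prof[tp_index[cols]]
      if (e$survival_modifier != 0)
        add <- add + e$survival_modifier * (ann$survival[cols] == "DNS")
      expr[rows, cols] <- expr[rows, cols] +
        matrix(add, length(rows), sum(cols), byrow = TRUE)
    }
  }

  structure(list(expr = expr, probes = probes, annotation = ann,
                 design = design, effects = effects),
            class = "sep_cohort")
}

#' @export
print.sep_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d probes x %d samples (%d planted genes)\n",
              nrow(x$expr), ncol(x$expr), length(x$effects)))
  print(table(group = x$annotation$group, timepoint = x$annotation$timepoint))
  invisible(x)
}

#' Default clinical simulation targets
#'
#' Per-group median/IQR targets for Day-1 clinical covariates of an ICU
#' sepsis/SIRS cohort: C-reactive protein (mg/L), white-cell, neutrophil,
#' lymphocyte, basophil and platelet counts (10^9/L), SOFA and APACHE II
#' severity scores. Values follow the admission-day summary statistics of a
#' four-arm severe-inflammation cohort.
#'
#' @return data.frame with columns group, variable, median, q1, q3, integer.
#' @export
clinical_targets <- function() {
  rb <- function(group, variable, median, q1, q3, integer = FALSE)
    data.frame(group = group, variable = variable, median = median,
               q1 = q1, q3 = q3, integer = integer, stringsAsFactors = FALSE)
  rbind(
    rb("SIRS", "CRP", 26, 5, 51),      rb("ABDM", "CRP", 216, 104, 336),
    rb("PLMN", "CRP", 197, 117, 280),
    rb("SIRS", "WBC", 14.9, 9.3, 21.2), rb("ABDM", "WBC", 15.8, 11.7, 19.4),
    rb("PLMN", "WBC", 15.8, 10.2, 22.4),
    rb("SIRS", "Neutrophils", 12.4, 7.3, 18.8),
    rb("ABDM", "Neutrophils", 12.8, 9.6, 17.3),
    rb("PLMN", "Neutrophils", 13.4, 8.6, 20.2),
    rb("SIRS", "Lymphocytes", 1.0, 0.6, 1.5),
    rb("ABDM", "Lymphocytes", 0.7, 0.5, 1.1),
    rb("PLMN", "Lymphocytes", 0.6, 0.4, 1.0),
    rb("SIRS", "Platelets", 191, 158, 234, TRUE),
    rb("ABDM", "Platelets", 205, 133, 301, TRUE),
    rb("PLMN", "Platelets", 206, 143, 284, TRUE),
    rb("SIRS", "SOFA", 16, 14, 20, TRUE), rb("ABDM", "SOFA", 17, 14, 19, TRUE),
    rb("PLMN", "SOFA", 17, 15, 19, TRUE),
    rb("SIRS", "APACHE", 30, 27, 34, TRUE), rb("ABDM", "APACHE", 31, 24, 37, TRUE),
    rb("PLMN", "APACHE", 31, 23, 40, TRUE)
  )
}

#' Fit a log-normal to a median/IQR target
#'
#' Quartile matching on the log scale: `meanlog = log(median)`,
#' `sdlog = (log(q3) - log(q1)) / (2 * 0.67449)` (quartiles of the standard
#' normal sit at +/- 0.67449 SD).
#'
#' @param median,q1,q3 Target median and interquartile bounds (> 0, q1 <= q3).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
lognormal_from_iqr <- function(median, q1, q3) {
  if (median <= 0 || q1 <= 0) stop("log-normal targets must be positive")
  if (q1 > q3) stop("inverted IQR bounds")
  c(meanlog = log(median),
    sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Simulate Day-1 clinical covariates
#'
#' Draws each clinical variable log-normal with parameters solved from the
#' per-group median/IQR targets (see [lognormal_from_iqr()]); integer-valued
#' variables (counts, severity scores) are rounded. A collapsed IQR (q1 = q3 =
#' median) yields the median exactly. APACHE II is a Day-1-only score by
#' construction.
#'
#' @param design A [cohort_design()].
#' @param targets Target table as from [clinical_targets()].
#' @param seed Seed; defaults to `design$seed + 1` so the clinical table is
#'   independent of, but locked to, the expression draw.
#' @return data.frame in long format: subject_id, group, variable, value.
#' @export
simulate_clinical <- function(design, targets = clinical_targets(),
                              seed = design$seed + 1L) {
  stopifnot(inherits(design, "cohort_design"),
            all(c("group", "variable", "median", "q1", "q3") %in% names(targets)))
  if (any(targets$q1 > targets$q3)) stop("inverted IQR bounds in targets")
  local_seed(seed)
  grp <- rep(names(design$group_sizes), design$group_sizes)
  subject_id <- sprintf("%s%03d", grp,
                        unlist(lapply(design$group_sizes, seq_len), use.names = FALSE))
  out <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    idx <- which(grp == tg$group)
    if (!length(idx)) return(NULL)
    if (tg$q1 == tg$median && tg$q3 == tg$median) {
      v <- rep(tg$median, length(idx))
    } else {
      par <- lognormal_from_iqr(tg$median, tg$q1, tg$q3)
      v <- stats::rlnorm(length(idx), par["meanlog"], par["sdlog"])
    }
    if (isTRUE(tg$integer)) v <- round(v)
    data.frame(subject_id = subject_id[idx], group = tg$group,
               variable = tg$variable, value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Realized fold change of a gene in a generated cohort
#'
#' Validation helper: the signed fold change ([fold_change()]) between two
#' groups at one timepoint, averaging over a gene's probes.
#'
#' @param cohort A `sep_cohort`.
#' @param gene Gene symbol.
#' @param group_a,group_b Group labels (numerator, denominator).
#' @param timepoint Timepoint label.
#' @return Signed linear fold change.
#' @export
realized_fold_change <- function(cohort, gene, group_a, group_b, timepoint = "D1") {
  stopifnot(inherits(cohort, "sep_cohort"))
  rows <- which(cohort$probes$gene == gene)
  if (!length(rows)) stop("gene not in cohort: ", gene)
  ann <- cohort$annotation
  ca <- ann$sample_id[ann$group %in% group_a & ann$timepoint == timepoint]
  cb <- ann$sample_id[ann$group %in% group_b & ann$timepoint == timepoint]
  if (!length(ca) || !length(cb)) stop("empty group selection")
  fold_change(colMeans(cohort$expr[rows, ca, drop = FALSE]),
              colMeans(cohort$expr[rows, cb, drop = FALSE]))
}

## ---- TSV round trip ----

#' Write a cohort to TSV files
#'
#' Expression as probes-in-rows TSV (first column `probe_id`, header = sample
#' IDs), annotation and probe tables alongside.
#'
#' @param cohort A `sep_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sep_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             probes = file.path(dir, "probes.tsv"))
  write_expression_tsv(cohort$expr, paths["expr"])
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$probes, paths["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @param expr Probes x samples numeric matrix.
#' @param path File path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#' @param path File path.
#' @return Probes x samples numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing expression/annotation/probes TSVs.
#' @return A `sep_cohort` (without design/effects provenance).
#' @export
read_cohort <- function(dir) {
  structure(list(expr = read_expression_tsv(file.path(dir, "expression.tsv")),
                 probes = utils::read.delim(file.path(dir, "probes.tsv"),
                                            stringsAsFactors = FALSE),
                 annotation = utils::read.delim(file.path(dir, "annotation.tsv"),
                                                stringsAsFactors = FALSE),
                 design = NULL, effects = list()),
            class = "sep_cohort")
}
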