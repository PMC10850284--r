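#' Reference diagnostic performance tables
#'
#' Published Day-1 single-marker diagnostic summaries for the
#' indicators-of-inflammation (IoI) and SIRS-or-sepsis (SoS) biomarker sets
#' (per-probe fold change, AUC, cut-off, percent sensitivity/specificity,
#' likelihood ratios, predictive values), and the SoS 5-gene signature's
#' per-comparison ROC summary (AUC, standard error, 90% CI and the rule-in /
#' rule-out cut-off rows). These serve as worked inputs for the package's
#' arithmetic: likelihood ratios recompute from the printed
#' sensitivity/specificity pairs via [likelihood_ratios()], and the CI bounds
#' from AUC and SE via [auc_ci()].
#'
#' @param which `"ioi"`, `"sos"` (single markers) or `"sos_panel"`.
#' @return data.frame.
#' @export
reference_table <- function(which = c("ioi", "sos", "sos_panel")) {
  which <- match.arg(which)
  file <- switch(which,
                 ioi = "ioi_day1_reference.tsv",
                 sos = "sos_day1_reference.tsv",
                 sos_panel = "sos_panel_reference.tsv")
  utils::read.delim(system.file("extdata", file, package = "sepsig"),
                    stringsAsFactors = FALSE)
}

#' Bookkeeping counts of the discovery array screen
#'
#' Entity counts of the discovery cohort's quality/filtering/ANOVA funnel:
#' total probes on the array, probes surviving the expression-range and
#' sex-linked-gene filters, the number of genes blacklisted, and probes
#' retained by the group-wise ANOVA at BH-FDR p <= 0.05. The ANOVA retention
#' percentage recomputes as `100 * anova_retained / filtered_entities`.
#'
#' @return Named list of integer counts.
#' @export
reference_counts <- function() {
  list(total_entities = 50739L, filtered_entities = 50728L,
       blacklisted_genes = 6L, anova_retained = 46227L)
}

#' Recompute likelihood ratios for a reference table
#'
#' Applies [likelihood_ratios()] to every printed sensitivity/specificity
#' pair and returns the table with `lr_pos_calc`/`lr_neg_calc` columns plus
#' the rounded-agreement deviations against the printed values.
#'
#' @param table A data.frame with `sensitivity_pct`, `specificity_pct`,
#'   `lr_pos`, `lr_neg` columns (see [reference_table()]).
#' @param digits Rounding used by the printed table (2 for single markers,
#'   4 for the panel summary).
#' @return The table with `lr_pos_calc`, `lr_neg_calc`, `lr_pos_dev`,
#'   `lr_neg_dev` columns appended.
#' @export
recompute_likelihood_ratios <- function(table, digits = 2) {
  lr <- t(mapply(likelihood_ratios, table$sensitivity_pct, table$specificity_pct))
  table$lr_pos_calc <- round(lr[, "lr_pos"], digits)
  table$lr_neg_calc <- round(lr[, "lr_neg"], digits)
  table$lr_pos_dev <- abs(table$lr_pos_calc - table$lr_pos)
  table$lr_neg_dev <- abs(table$lr_neg_calc - table$lr_neg)
  table
}
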