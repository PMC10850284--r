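#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks of the end-to-end discovery
#' pipeline into one validated object. Any block can be overridden; the
#' global seed propagates deterministically to every stage.
#'
#' @param design A [cohort_design()] (the simulate stage), or `NULL` when
#'   `input_dir` points at an existing cohort on disk.
#' @param effects Planted effects for the simulate stage.
#' @param input_dir Directory of a cohort written by [write_cohort()]; used
#'   instead of simulation when given.
#' @param ann An [ann_config()] or `NULL` to skip stepwise ANN selection.
#' @param forest A [forest_config()] or `NULL` to skip forest ranking.
#' @param panels List of [panel_def()] objects to evaluate.
#' @param comparisons List of comparisons, each a list with `positive`,
#'   `negative` (group label vectors) and optional `timepoint`.
#' @param diff_comparison A single comparison used for the differential
#'   table, same shape as one element of `comparisons`.
#' @param seed Global seed; stage seeds derive from it.
#' @param out_dir Output directory for stage TSVs and the manifest; `NULL`
#'   keeps results in memory only.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            effects = ioi_effects(),
                            input_dir = NULL,
                            ann = NULL,
                            forest = forest_config(),
                            panels = list(panel_def("FAM20A+OLAH")),
                            comparisons = list(list(
                              positive = c("SIRS", "ABDM", "PLMN"),
                              negative = "CNTRL", timepoint = "D1")),
                            diff_comparison = comparisons[[1]],
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(is.null(design) || inherits(design, "cohort_design"),
            is.null(ann) || inherits(ann, "ann_config"),
            is.null(forest) || inherits(forest, "forest_config"))
  if (is.null(design) && is.null(input_dir))
    stop("either a design (simulate) or an input_dir (load) is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(design = design, effects = effects, input_dir = input_dir,
                 ann = ann, forest = forest, panels = panels,
                 comparisons = comparisons, diff_comparison = diff_comparison,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' A thin front-end over [pipeline_config()]: recognised top-level keys are
#' `seed`, `out_dir`, `input_dir`, `design` (fields of [cohort_design()]),
#' `effects` (list of gene/groups/fold_change entries), `ann`
#' ([ann_config()] fields), `forest` ([forest_config()] fields), `panels`
#' (signature strings or preset names) and `comparisons`.
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(y$input_dir)) args$input_dir <- y$input_dir
  if (!is.null(y$design)) args$design <- do.call(cohort_design, y$design)
  if (!is.null(y$effects))
    args$effects <- lapply(y$effects, function(e)
      planted_effect(e$gene, unlist(e$groups), e$fold_change))
  if (!is.null(y$ann)) args$ann <- do.call(ann_config, y$ann)
  if (!is.null(y$forest)) args$forest <- do.call(forest_config, y$forest)
  if (!is.null(y$panels)) {
    presets <- panel_presets()$name
    args$panels <- lapply(y$panels, function(p)
      if (p %in% presets) panel_presets(p) else panel_def(p))
  }
  if (!is.null(y$comparisons)) args$comparisons <- y$comparisons
  do.call(pipeline_config, args)
}

#' Run the end-to-end discovery pipeline
#'
#' Executes the enabled stages in order — simulate (or load), preprocess,
#' differential statistics, stepwise ANN selection, random-forest ranking,
#' panel evaluation — and, when `out_dir` is set, writes every stage table
#' as TSV plus a run manifest (config echo, package version, seed, per-stage
#' wall time). A stage failure aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result` with entries `cohort`,
#'   `diff` (differential table), `ann` (stepwise result or `NULL`),
#'   `forest` (importance ranking or `NULL`), `panel_reports` (list of
#'   [evaluate_panel()] reports) and `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(design = cohort_design(n_probes = 200, seed = 3))
#' res <- run_pipeline(cfg)
#' res$panel_reports[[1]]
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_seeds <- derive_seeds(config$seed, 5)
  times <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    times[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  cohort <- tick("simulate", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else {
      d <- config$design; d$seed <- stage_seeds[1]
      generate_cohort(d, config$effects)
    }
  })
  cohort <- tick("preprocess", preprocess_cohort(cohort))

  dc <- config$diff_comparison
  diff <- tick("diffstats",
               diff_table(cohort, dc$positive, dc$negative,
                          timepoint = if (is.null(dc$timepoint)) "D1" else dc$timepoint))

  ann_res <- NULL
  if (!is.null(config$ann)) {
    ann_res <- tick("ann_select", {
      cfg <- config$ann; cfg$seed <- stage_seeds[2]
      xy <- comparison_xy(cohort, dc)
      stepwise_select(xy$x, xy$y, config = cfg)
    })
  }

  forest_res <- NULL
  if (!is.null(config$forest)) {
    forest_res <- tick("forest_rank", {
      cfg <- config$forest; cfg$seed <- stage_seeds[3]
      xy <- comparison_xy(cohort, dc)
      rank_importance(xy$x, factor(xy$y), cfg)
    })
  }

  panel_reports <- tick("panelroc", {
    out <- list()
    for (p in config$panels) for (cmp in config$comparisons) {
      rep <- evaluate_panel(p, cohort, cmp$positive, cmp$negative,
                            timepoint = if (is.null(cmp$timepoint)) "D1"
                            else cmp$timepoint)
      out[[length(out) + 1L]] <- rep
    }
    out
  })

  manifest <- list(package_version = as.character(utils::packageVersion("sepsig")),
                   seed = config$seed, stage_seconds = as.list(times),
                   n_probes = nrow(cohort$expr), n_samples = ncol(cohort$expr),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- structure(list(cohort = cohort, diff = diff, ann = ann_res,
                           forest = forest_res, panel_reports = panel_reports,
                           manifest = manifest, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

## Extract a samples x genes matrix + 0/1 labels for one comparison,
## collapsing duplicate probes of a gene by mean.
comparison_xy <- function(cohort, cmp) {
  tp <- if (is.null(cmp$timepoint)) "D1" else cmp$timepoint
  ann <- cohort$annotation
  sel <- if (is.null(tp)) rep(TRUE, nrow(ann)) else ann$timepoint == tp
  ids <- ann$sample_id[sel & ann$group %in% c(cmp$positive, cmp$negative)]
  y <- as.integer(ann$group[match(ids, ann$sample_id)] %in% cmp$positive)
  gene_of <- cohort$probes$gene[match(rownames(cohort$expr), cohort$probes$probe_id)]
  sums <- rowsum(cohort$expr[, ids, drop = FALSE], gene_of)  # sorted by gene
  counts <- as.vector(table(gene_of))                        # same sorted order
  x <- t(sums / counts)
  list(x = x[, unique(gene_of), drop = FALSE], y = y, ids = ids)
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(result$cohort, dir)
  utils::write.table(result$diff, file.path(dir, "diff_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$ann)) {
    st <- data.frame(step = seq_along(result$ann$selected),
                     gene = result$ann$selected,
                     mean_val_error = result$ann$step_errors)
    utils::write.table(st, file.path(dir, "ann_stepwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$forest))
    utils::write.table(result$forest$importance,
                       file.path(dir, "rf_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  panel_rows <- do.call(rbind, lapply(result$panel_reports, function(r) {
    if (inherits(r, "panel_eval_missing"))
      data.frame(panel = r$panel$name, auc = NA, se = NA,
                 missing = paste(r$missing_genes, collapse = ","))
    else data.frame(panel = r$panel$name, auc = r$roc$auc, se = r$roc$se,
                    missing = "")
  }))
  utils::write.table(panel_rows, file.path(dir, "panel_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  cohort: %d probes x %d samples\n",
              nrow(x$cohort$expr), ncol(x$cohort$expr)))
  cat(sprintf("  differential table: %d probes (%d with q < 0.05)\n",
              nrow(x$diff), sum(x$diff$q < 0.05)))
  if (!is.null(x$ann))
    cat("  ANN panel:", paste(x$ann$selected, collapse = " + "), "\n")
  if (!is.null(x$forest))
    cat(sprintf("  forest OOB error: %.2f%%\n", 100 * x$forest$oob_error))
  for (r in x$panel_reports)
    if (!inherits(r, "panel_eval_missing"))
      cat(sprintf("  panel %s: AUC %.4f\n", r$panel$name, r$roc$auc))
  invisible(x)
}
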