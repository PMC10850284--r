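#' Random-forest configuration
#'
#' @param n_trees Trees per forest (default 2001).
#' @param mtry Features tried per split; `NULL` picks `floor(sqrt(p))` at fit
#'   time. (Panel-sized inputs in the discovery workflow used 31 for the
#'   inflammation panel and 11 for the SIRS/sepsis panel.)
#' @param train_fraction Fraction of samples in the training cohort; the rest
#'   form the held-out test cohort.
#' @param seed Seed.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 2001L, mtry = NULL, train_fraction = 0.75,
                          seed = 1L) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "forest_config")
}

#' Random-forest importance ranking
#'
#' Fits a random forest on a stratified `train_fraction` split and reports
#' both importance measures (permutation mean decrease in accuracy, mean
#' decrease in Gini impurity) together with the out-of-bag error and the
#' held-out test error.
#'
#' @param x Samples x genes numeric matrix.
#' @param y Class labels (2+ classes; coerced to factor).
#' @param config A [forest_config()].
#' @return Object of class `rf_importance`: `importance` data.frame (gene,
#'   mean_decrease_accuracy, mean_decrease_gini), `oob_error`, `test_error`,
#'   and the fitted forest.
#' @export
rank_importance <- function(x, y, config = forest_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  stopifnot(nrow(x) == length(y))
  local_seed(config$seed)
  tr <- unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(config$train_fraction * length(idx))))
  }))
  te <- setdiff(seq_along(y), tr)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    min(config$mtry, ncol(x))
  fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                    ntree = config$n_trees, mtry = mtry,
                                    importance = TRUE)
  oob <- unname(fit$err.rate[config$n_trees, "OOB"])
  test_error <- if (length(te))
    mean(predict(fit, x[te, , drop = FALSE]) != y[te]) else NA_real_
  imp <- randomForest::importance(fit)
  structure(list(importance = data.frame(
    gene = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE),
    oob_error = oob, test_error = test_error, forest = fit,
    config = config), class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat(sprintf("Random-forest ranking (%d trees): OOB error %.2f%%, test error %s\n",
              x$config$n_trees, 100 * x$oob_error,
              if (is.na(x$test_error)) "NA" else sprintf("%.2f%%", 100 * x$test_error)))
  ord <- order(-x$importance$mean_decrease_accuracy)
  print(utils::head(x$importance[ord, ], 10), row.names = FALSE)
  invisible(x)
}

#' Iterative least-important elimination
#'
#' Repeatedly refits [rank_importance()] and removes the least important
#' gene(s) by mean decrease in accuracy (ties broken by gene name) until
#' `target_size` genes remain. Importances are recomputed from scratch every
#' round; the trace records the retained set and OOB error per round.
#'
#' @param x Samples x genes matrix.
#' @param y Class labels.
#' @param config A [forest_config()].
#' @param target_size Panel size to stop at (must be < ncol(x)).
#' @param drop_per_round Genes removed per round (default 1).
#' @return Object of class `rf_elimination`: `rounds` (list of retained gene
#'   sets + OOB errors), `final_panel`, `final_oob_error`.
#' @export
iterative_eliminate <- function(x, y, config = forest_config(), target_size,
                                drop_per_round = 1L) {
  x <- as.matrix(x)
  if (target_size >= ncol(x)) stop("target_size must be smaller than the gene count")
  stopifnot(target_size >= 1, drop_per_round >= 1)
  seeds <- derive_seeds(config$seed, ncol(x) + 1L)  # one per round + final refit
  keep <- colnames(x)
  rounds <- list()
  r <- 0L
  while (length(keep) > target_size) {
    r <- r + 1L
    cfg <- config; cfg$seed <- seeds[r]
    rk <- rank_importance(x[, keep, drop = FALSE], y, cfg)
    rounds[[r]] <- list(genes = keep, oob_error = rk$oob_error)
    imp <- rk$importance
    ord <- order(imp$mean_decrease_accuracy, imp$gene)  # least important first
    n_drop <- min(drop_per_round, length(keep) - target_size)
    keep <- setdiff(keep, imp$gene[ord[seq_len(n_drop)]])
  }
  cfg <- config; cfg$seed <- seeds[r + 1L]
  final_fit <- rank_importance(x[, keep, drop = FALSE], y, cfg)
  structure(list(rounds = rounds, final_panel = keep,
                 final_oob_error = final_fit$oob_error,
                 final_importance = final_fit$importance,
                 config = config), class = "rf_elimination")
}

#' @export
print.rf_elimination <- function(x, ...) {
  cat(sprintf("Iterative RF elimination: %d round(s), final panel of %d gene(s)\n",
              length(x$rounds), length(x$final_panel)))
  cat("  final panel:", paste(x$final_panel, collapse = ", "), "\n")
  cat(sprintf("  final OOB error: %.2f%%\n", 100 * x$final_oob_error))
  invisible(x)
}
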