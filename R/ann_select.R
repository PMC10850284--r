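## Stratified train/test/validation split of indices by class.
## Redraws (up to a cap) if any split misses a class.
stratified_split <- function(y, fractions, max_retry = 20) {
  for (attempt in seq_len(max_retry)) {
    parts <- list(train = integer(0), test = integer(0), val = integer(0))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_te <- round(fractions[2] * n)
      n_tr <- max(1L, min(n_tr, n - 2L))
      n_te <- max(1L, min(n_te, n - n_tr - 1L))
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$test <- c(parts$test, idx[n_tr + seq_len(n_te)])
      parts$val <- c(parts$val, idx[(n_tr + n_te + 1L):n])
    }
    ok <- all(vapply(parts, function(ix) length(unique(y[ix])) == length(unique(y)), TRUE))
    if (ok) return(parts)
  }
  stop("could not draw a stratified split containing every class")
}

#' Monte-Carlo cross-validated error of a candidate gene set
#'
#' For each of `n_resamples` repeats: draw a fresh stratified
#' train/test/validation split, initialise a fresh perceptron, train with
#' early stopping against the test split, and record the error of the
#' validation (blind) split. Returns the mean across repeats. Per-resample
#' seeds derive deterministically from `seed`, so the estimate is exactly
#' reproducible.
#'
#' @param x Samples x features numeric matrix (the candidate gene columns).
#' @param y Labels in `{0, 1}`.
#' @param config An [ann_config()].
#' @param seed Master seed (default `config$seed`).
#' @return Mean validation error (MSE by default; see `config$metric`).
#' @export
mc_error <- function(x, y, config = ann_config(), seed = config$seed) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), ncol(x) >= 1)
  seeds <- derive_seeds(seed, config$n_resamples)
  errs <- vapply(seeds, function(s) {
    local_seed(s)
    sp <- stratified_split(y, config$split_fractions)
    model <- init_mlp(ncol(x), config, seed = s)
    fit <- train_mlp(model, x[sp$train, , drop = FALSE], y[sp$train],
                     x[sp$test, , drop = FALSE], y[sp$test],
                     config = config, seed = s + 1L)
    pred <- predict(fit, x[sp$val, , drop = FALSE])
    if (config$metric == "mse") mean((pred - y[sp$val])^2)
    else mean(abs(pred - y[sp$val]))
  }, 0)
  mean(errs)
}

#' Stepwise neural-network feature selection
#'
#' The exhaustive forward search: step 1 trains one model per candidate gene
#' and keeps the gene with the lowest Monte-Carlo validation error; step k
#' appends each remaining gene to the current set, re-evaluates, and keeps
#' the best extension. The search stops when the panel reaches
#' `max_panel_size` or the best extension fails to improve the mean error by
#' at least `improve_tol`.
#'
#' @param x Samples x genes numeric matrix (normalized log2 expression).
#' @param y Labels in `{0, 1}` (1 = positive class, e.g. sepsis).
#' @param pool Candidate gene names (default: all columns of `x`).
#' @param config An [ann_config()].
#' @return An object of class `ann_stepwise`: `selected` (ordered genes),
#'   `step_errors` (mean validation error after each accepted step) and
#'   `candidate_errors` (per-step named lists of every candidate's error).
#' @export
stepwise_select <- function(x, y, pool = colnames(x), config = ann_config()) {
  x <- as.matrix(x)
  if (is.null(pool) || !length(pool)) stop("empty candidate pool")
  stopifnot(all(pool %in% colnames(x)), nrow(x) == length(y))
  selected <- character(0)
  step_errors <- numeric(0)
  candidate_errors <- list()
  remaining <- pool
  step_seeds <- derive_seeds(config$seed, config$max_panel_size)
  for (step in seq_len(min(config$max_panel_size, length(pool)))) {
    errs <- vapply(seq_along(remaining), function(i) {
      cols <- c(selected, remaining[i])
      mc_error(x[, cols, drop = FALSE], y, config,
               seed = (step_seeds[step] + i) %% .Machine$integer.max)
    }, 0)
    names(errs) <- remaining
    candidate_errors[[step]] <- errs
    best <- which.min(errs)
    if (length(selected) &&
        errs[best] > step_errors[length(step_errors)] - config$improve_tol) {
      candidate_errors[[step]] <- errs  # recorded, but no gene accepted
      break
    }
    selected <- c(selected, remaining[best])
    step_errors <- c(step_errors, unname(errs[best]))
    remaining <- remaining[-best]
    if (!length(remaining)) break
  }
  structure(list(selected = selected, step_errors = step_errors,
                 candidate_errors = candidate_errors, config = config),
            class = "ann_stepwise")
}

#' @export
print.ann_stepwise <- function(x, ...) {
  cat("Stepwise ANN selection\n")
  if (!length(x$selected)) { cat("  (no gene accepted)\n"); return(invisible(x)) }
  for (i in seq_along(x$selected))
    cat(sprintf("  step %d: + %-12s mean validation error %.4f\n",
                i, x$selected[i], x$step_errors[i]))
  invisible(x)
}

#' @export
summary.ann_stepwise <- function(object, ...) {
  cat(sprintf("Selected panel (%d gene(s)): %s\n", length(object$selected),
              paste(object$selected, collapse = " + ")))
  cat(sprintf("Final mean validation error: %.4f over %d resamples\n",
              utils::tail(object$step_errors, 1), object$config$n_resamples))
  invisible(object)
}

#' Stability of the stepwise selection across repeated runs
#'
#' Re-runs the whole stepwise procedure under several master seeds and
#' reports how often each gene is selected (and how often it is the first
#' pick) — the repeated-run stability assessment for a given cohort size.
#'
#' @param x,y,pool,config As in [stepwise_select()].
#' @param runs Number of repeated runs.
#' @return data.frame: gene, times_selected, times_first, frequency.
#' @export
stability_runs <- function(x, y, pool = colnames(x), config = ann_config(),
                           runs = 5) {
  seeds <- derive_seeds(config$seed, runs)
  picks <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    stepwise_select(x, y, pool, cfg)$selected
  })
  all_genes <- sort(unique(unlist(picks)))
  data.frame(gene = all_genes,
             times_selected = vapply(all_genes, function(g)
               sum(vapply(picks, function(p) g %in% p, TRUE)), 0L),
             times_first = vapply(all_genes, function(g)
               sum(vapply(picks, function(p) length(p) && p[1] == g, TRUE)), 0L),
             frequency = vapply(all_genes, function(g)
               mean(vapply(picks, function(p) g %in% p, TRUE)), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
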