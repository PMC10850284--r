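#' Configuration for the stepwise neural-network selector
#'
#' Hyperparameters of the three-layer perceptron and its Monte-Carlo
#' cross-validation protocol: two logistic hidden units, learning rate 0.1,
#' momentum 0.5, weights initialised Normal(0, 0.1^2), stratified 60/20/20
#' train/test/validation splits repeated 50 times. The output unit codes 0
#' for the negative class and 1 for the positive (e.g. sepsis) class.
#'
#' @param n_hidden Hidden units.
#' @param learning_rate,momentum Online backpropagation step size and
#'   momentum coefficient.
#' @param init_sd SD of the Normal(0, sd^2) weight initialisation.
#' @param split_fractions Train/test/validation fractions (sum to 1).
#' @param n_resamples Monte-Carlo resampling repeats per candidate set.
#' @param max_epochs Epoch budget per fit.
#' @param patience Epochs without test-split improvement before early stop.
#' @param early_stop Checkpoint at best test error (default) or train the
#'   full epoch budget.
#' @param max_panel_size Largest panel the stepwise search may grow.
#' @param improve_tol Minimum mean-error improvement to accept another step.
#' @param metric Validation error used for ranking: mean squared error
#'   (default) or mean absolute error.
#' @param seed Master seed; resample seeds derive from it deterministically.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(n_hidden = 2L, learning_rate = 0.1, momentum = 0.5,
                       init_sd = 0.1, split_fractions = c(0.6, 0.2, 0.2),
                       n_resamples = 50L, max_epochs = 300L, patience = 20L,
                       early_stop = TRUE, max_panel_size = 10L,
                       improve_tol = 1e-4, metric = c("mse", "mae"),
                       seed = 1L) {
  stopifnot(n_hidden >= 1, learning_rate > 0, momentum >= 0, init_sd >= 0,
            length(split_fractions) == 3, all(split_fractions > 0),
            abs(sum(split_fractions) - 1) < 1e-8,
            n_resamples >= 1, max_epochs >= 1, patience >= 1,
            max_panel_size >= 1)
  structure(list(n_hidden = as.integer(n_hidden), learning_rate = learning_rate,
                 momentum = momentum, init_sd = init_sd,
                 split_fractions = split_fractions,
                 n_resamples = as.integer(n_resamples),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), early_stop = early_stop,
                 max_panel_size = as.integer(max_panel_size),
                 improve_tol = improve_tol, metric = match.arg(metric),
                 seed = as.integer(seed)),
            class = "ann_config")
}

#' Initialise a multilayer perceptron
#'
#' All weights drawn Normal(0, `init_sd`^2), biases zero. With `init_sd = 0`
#' the network outputs exactly 0.5 everywhere (logistic of a zero net input).
#'
#' @param n_inputs Number of input features (>= 1).
#' @param config An [ann_config()].
#' @param seed Seed for the weight draw (default `config$seed`).
#' @return An object of class `sepsig_mlp` holding `W1` (inputs x hidden),
#'   `b1`, `W2` (hidden), `b2`.
#' @export
init_mlp <- function(n_inputs, config = ann_config(), seed = config$seed) {
  stopifnot(n_inputs >= 1)
  local_seed(seed)
  h <- config$n_hidden
  structure(list(W1 = matrix(stats::rnorm(n_inputs * h, 0, config$init_sd),
                             n_inputs, h),
                 b1 = rep(0, h), W2 = stats::rnorm(h, 0, config$init_sd),
                 b2 = 0, n_hidden = h, config = config),
            class = "sepsig_mlp")
}

#' @export
print.sepsig_mlp <- function(x, ...) {
  cat(sprintf("3-layer perceptron: %d input(s) -> %d logistic hidden -> 1 logistic output\n",
              nrow(x$W1), x$n_hidden))
  if (!is.null(x$trained) && x$trained)
    cat(sprintf("  trained %d epoch(s); best test MSE %.4g at epoch %d\n",
                x$epochs_run, min(x$test_trace), x$best_epoch))
  invisible(x)
}

#' Train a perceptron by online backpropagation
#'
#' Per-sample gradient steps on squared error `0.5 * (o - y)^2` of the
#' logistic output, with momentum `alpha * (previous update)`; samples are
#' visited in a fresh random order each epoch. Training stops at the epoch
#' budget or, with early stopping, after `patience` epochs without
#' improvement of the test-split error; the returned model carries the
#' weights at the best test error.
#'
#' @param model A `sepsig_mlp` from [init_mlp()].
#' @param x Samples x features numeric matrix (training split).
#' @param y Labels in `{0, 1}`.
#' @param x_test,y_test Optional test split monitoring generalisation during
#'   training; when absent the training error is monitored.
#' @param config An [ann_config()]; defaults to the model's.
#' @param seed Seed for the per-epoch sample orders.
#' @return The trained `sepsig_mlp` with `test_trace`, `best_epoch`,
#'   `epochs_run` fields.
#' @export
train_mlp <- function(model, x, y, x_test = NULL, y_test = NULL,
                      config = model$config, seed = config$seed) {
  x <- as.matrix(x)
  stopifnot(inherits(model, "sepsig_mlp"), nrow(x) == length(y),
            ncol(x) == nrow(model$W1))
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (is.null(x_test)) {
    x_test <- matrix(0, 0, ncol(x)); y_test <- numeric(0)
  } else {
    x_test <- as.matrix(x_test)
  }
  local_seed(seed)
  fit <- mlp_train_cpp(x, as.numeric(y), x_test, as.numeric(y_test),
                       model$W1, model$b1, model$W2, model$b2,
                       config$learning_rate, config$momentum,
                       config$max_epochs, config$patience,
                       config$early_stop)
  model$W1 <- fit$W1; model$b1 <- fit$b1; model$W2 <- fit$W2; model$b2 <- fit$b2
  model$test_trace <- fit$test_trace
  model$best_epoch <- fit$best_epoch
  model$epochs_run <- fit$epochs_run
  model$trained <- TRUE
  model
}

#' @describeIn train_mlp Forward-pass predictions in (0, 1).
#' @param object A `sepsig_mlp`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @export
predict.sepsig_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == nrow(object$W1))
  as.numeric(mlp_forward_cpp(newdata, object$W1, object$b1, object$W2, object$b2))
}
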