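#' @useDynLib sepsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Seed the RNG for the duration of the calling function, restoring prior
## RNG state on exit: every generator is seedable without clobbering the
## caller's random stream.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

## Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  local_seed(seed)
  sample.int(.Machine$integer.max, n)
}
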