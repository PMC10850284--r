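# Small shared fixtures, all generated in code.

tiny_design <- function(n_probes = 60, seed = 1,
                        sizes = c(CNTRL = 10L, SIRS = 8L, ABDM = 9L, PLMN = 12L),
                        ...) {
  cohort_design(group_sizes = sizes, n_probes = n_probes, seed = seed, ...)
}

# Two-class expression matrix with one separating gene among noise genes.
sep_xy <- function(n_per_class = 30, n_noise = 4, gap = 3, sd = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(c(rnorm(n_per_class, 0, sd), rnorm(n_per_class, gap, sd)),
              ncol = 1, dimnames = list(NULL, "SIG"))
  if (n_noise > 0) {
    noise <- matrix(rnorm(2 * n_per_class * n_noise, 0, sd),
                    2 * n_per_class, n_noise,
                    dimnames = list(NULL, paste0("NOISE", seq_len(n_noise))))
    x <- cbind(x, noise)
  }
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# Exhaustive pair-counting AUC oracle (ties half-counted).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Brute-force BH step-up: sort, adjust, cummin from largest rank, unsort.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent forward/loss for the 3-layer perceptron, used as the
# numeric-gradient oracle for one backprop step.
mlp_loss <- function(theta, p, h, x, y) {
  W1 <- matrix(theta[1:(p * h)], p, h)
  b1 <- theta[p * h + 1:h]
  W2 <- theta[p * h + h + 1:h]
  b2 <- theta[length(theta)]
  sig <- function(z) 1 / (1 + exp(-z))
  o <- sig(sum(W2 * sig(drop(x %*% W1) + b1)) + b2)
  0.5 * (o - y)^2
}

num_grad <- function(theta, ...) {
  h <- 1e-5
  vapply(seq_along(theta), function(i) {
    e <- replace(numeric(length(theta)), i, h)
    (mlp_loss(theta + e, ...) - mlp_loss(theta - e, ...)) / (2 * h)
  }, 0)
}

theta_of <- function(m) c(as.vector(m$W1), m$b1, m$W2, m$b2)

# Full-enumeration two-sided Mann-Whitney p (no ties assumed).
mw_enum <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  combos <- utils::combn(length(pooled), m)
  u_obs <- sum(outer(a, b, ">"))
  us <- apply(combos, 2, function(ix)
    sum(outer(pooled[ix], pooled[-ix], ">")))
  mu <- m * (length(b)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
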