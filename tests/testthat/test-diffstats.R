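test_that("signed fold change follows the +/-2^delta convention", {
  expect_equal(fold_change(c(5, 5), c(0, 0)), 32)
  expect_equal(fold_change(c(0, 0), c(2, 2)), -4)
  expect_equal(fold_change(1:3, 1:3), 1)
  expect_error(fold_change(numeric(0), 1), "empty")
  # antisymmetry away from equality, +1 at equality
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(7)
    fab <- fold_change(a, b); fba <- fold_change(b, a)
    if (abs(fab) > 1) expect_equal(fab, -fba) else expect_equal(fab, 1)
    expect_gte(abs(fab), 1)
  }
})

test_that("t-test matches the hand-computed pooled statistic", {
  tt <- t_test(c(1, 2, 3), c(4, 5, 6), welch = FALSE)
  # mean diff -3, pooled sd 1, se = sqrt(2/3) -> t = -3.674
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(tt$t, 3), -3.674)
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate: zero variance both sides, equal means
  expect_equal(t_test(c(2, 2), c(2, 2))$p, 1)
})

test_that("t-test has power at a planted 3-sigma shift", {
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    t_test(rnorm(30), rnorm(30, 3))$p < 1e-6
  }, TRUE)
  expect_gte(mean(rej), 0.99)
})

test_that("one-way ANOVA reproduces hand sums of squares and conventions", {
  r <- one_way_anova(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$f, 16)  # SSB 16 over 2 df, SSW 1.5 over 3 df
  expect_equal(r$p, pf(16, 2, 3, lower.tail = FALSE))
  degen <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(degen$f, Inf)
  expect_equal(degen$p, 0)
  flat <- one_way_anova(list(c(3, 3), c(3, 3)))
  expect_equal(flat$f, 0)
  expect_equal(flat$p, 1)
})

test_that("vectorised per-probe ANOVA agrees with oneway.test", {
  set.seed(7)
  expr <- matrix(rnorm(50 * 24), 50, 24,
                 dimnames = list(paste0("p", 1:50), paste0("s", 1:24)))
  grp <- rep(c("A", "B", "C"), each = 8)
  fast <- sepsig:::anova_by_probe(expr, grp)
  for (i in c(1, 17, 50)) {
    ref <- oneway.test(expr[i, ] ~ factor(grp), var.equal = TRUE)
    expect_equal(fast$f[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fast$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)), c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("Mann-Whitney exact branch equals full enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    v <- sample(100, na + nb)  # distinct -> no ties
    a <- v[1:na]; b <- v[-(1:na)]
    expect_equal(mann_whitney(a, b)$p, mw_enum(a, b), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("Mann-Whitney detects a strong planted shift", {
  set.seed(9)
  crp_sirs <- rlnorm(42, log(26), 0.9)
  crp_sepsis <- rlnorm(141, log(202), 0.6)
  expect_lt(mann_whitney(crp_sepsis, crp_sirs)$p, 0.001)
})

test_that("PCA scores separate planted clusters and conserve variance", {
  set.seed(4)
  base <- rnorm(30)
  expr <- sapply(1:20, function(i) base + rnorm(30, 0, 0.05))
  expr <- t(expr)  # 20 probes x 30 samples, rank ~1 + noise
  dimnames(expr) <- list(paste0("p", 1:20), paste0("s", 1:30))
  pc <- pca_scores(expr, 2)
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.9)

  # two separated clusters: PC1 classifies perfectly
  expr2 <- cbind(matrix(rnorm(20 * 15, 0), 20), matrix(rnorm(20 * 15, 4), 20))
  dimnames(expr2) <- list(paste0("p", 1:20), paste0("s", 1:30))
  lab <- rep(c(0, 1), each = 15)
  pc2 <- pca_scores(expr2, 2)
  expect_equal(roc_auc(pc2$scores[, 1] * sign(cor(pc2$scores[, 1], lab)), lab)$auc, 1)

  # total variance preserved across the full decomposition
  pfull <- prcomp(t(expr2), center = TRUE)
  expect_equal(sum(pfull$sdev^2),
               sum(apply(t(expr2), 2, var)), tolerance = 1e-8)
  expect_error(pca_scores(expr2, 31), "rank")
})

test_that("diff_table recovers planted genes with controlled FDR ordering", {
  co <- generate_cohort(cohort_design(n_probes = 100, seed = 21),
                        ioi_effects()[1:3])
  co <- preprocess_cohort(co)
  dt <- diff_table(co, c("SIRS", "ABDM", "PLMN"), "CNTRL")
  top <- dt$gene[order(dt$p)][1:3]
  expect_setequal(top, c("CD177", "FAM20A", "MMP9"))
  expect_true(all(dt$q >= dt$p - 1e-15))
  expect_true(all(abs(dt$fc) >= 1))
})
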