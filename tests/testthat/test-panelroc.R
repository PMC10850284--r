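test_that("panel parsing handles signature strings and explicit signs", {
  p <- panel_def("CETP+CMTM5+MIA-MPP3-PLA2G7")
  expect_equal(p$terms$gene, c("CETP", "CMTM5", "MIA", "MPP3", "PLA2G7"))
  expect_equal(p$terms$sign, c(1, 1, 1, -1, -1))
  p2 <- panel_def(c("A", "B"), signs = c(1, -1))
  expect_equal(p2$terms$sign, c(1, -1))
  expect_error(panel_def("A+A"), "duplicate")
  expect_error(panel_def(character(0)), "at least one")
  sc <- panel_presets("septicyte_lab")
  expect_equal(sc$terms$gene, c("PLAC8", "PLA2G7", "LAMP1", "CEACAM4"))
  expect_equal(sc$terms$sign, c(1, -1, 1, -1))
})

test_that("composite scores are the signed sums and linear in the data", {
  m <- rbind(A = c(2, 1), B = c(0.5, 3))
  colnames(m) <- c("s1", "s2")
  sc <- composite_score(panel_def("A-B"), m)
  expect_equal(unname(sc), c(1.5, -2))
  one <- composite_score(panel_def("A", signs = 1), m)
  expect_equal(unname(one), unname(m["A", ]))
  shifted <- m; shifted["A", ] <- shifted["A", ] + 3
  expect_equal(composite_score(panel_def("A-B"), shifted), sc + 3)
  expect_error(composite_score(panel_def("A+Z"), m), "Z")
})

test_that("AUC equals exhaustive pair counting, with symmetries", {
  rc <- roc_auc(c(2, 0, 1, -1), c(1, 1, 0, 0))
  expect_equal(rc$auc, 3 / 4)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  set.seed(14)
  for (i in 1:30) {
    n1 <- sample(2:40, 1); n0 <- sample(2:40, 1)
    s <- c(rnorm(n1, 0.5), rnorm(n0))
    if (i %% 3 == 0) s <- round(s)  # force ties
    lab <- rep(c(1, 0), c(n1, n0))
    a <- roc_auc(s, lab)$auc
    expect_equal(a, auc_pairs(s, lab), tolerance = 1e-12)
    expect_equal(roc_auc(s, 1 - lab)$auc, 1 - a, tolerance = 1e-12)
    expect_equal(roc_auc(-s, lab)$auc, 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC curve area matches the pair-counting statistic", {
  set.seed(3)
  s <- round(rnorm(60), 1)
  lab <- rep(c(1, 0), 30)
  rc <- roc_auc(s, lab)
  fpr <- rev(1 - rc$specificity); tpr <- rev(rc$sensitivity)
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(trap, rc$auc, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(27)
  for (i in 1:5) {
    s <- rnorm(80) + rep(c(0.8, 0), each = 40)
    lab <- rep(c(1, 0), each = 40)
    expect_equal(roc_auc(s, lab)$auc,
                 as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE and the normal CI reproduce worked values", {
  se_at <- function(A, n1, n0) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) / (n1 * n0))
  }
  expect_equal(round(se_at(0.5, 10, 10), 4), 0.1323)
  s <- c(2, 0, 1, -1); lab <- c(1, 1, 0, 0)
  expect_equal(roc_auc(s, lab)$se, se_at(0.75, 2, 2), tolerance = 1e-12)

  expect_equal(auc_ci(0.9758, 0.01067, 0.90), c(0.9582, 0.9934),
               tolerance = 1e-4)
  expect_equal(auc_ci(0.7, 0, 0.90), c(0.7, 0.7))
  expect_equal(auc_ci(0.5, 0.1, 0.95), c(0.3040, 0.6960), tolerance = 1e-4)
  expect_equal(auc_ci(0.9842, 0.009643, 0.90)[2], 1)  # clipped at 1
})

test_that("likelihood ratios reproduce printed diagnostic-table values", {
  expect_equal(round(likelihood_ratios(98.80, 96.67)[["lr_pos"]], 2), 29.67)
  expect_equal(round(likelihood_ratios(96.80, 89.74)[["lr_pos"]], 4), 9.4347)
  expect_equal(likelihood_ratios(100, 100), c(lr_pos = Inf, lr_neg = 0))
  expect_equal(likelihood_ratios(0, 0), c(lr_pos = 0, lr_neg = Inf))
})

test_that("every reference likelihood ratio recomputes from its sens/spec pair", {
  for (tab in c("ioi", "sos")) {
    rec <- recompute_likelihood_ratios(reference_table(tab), digits = 2)
    expect_true(all(rec$lr_pos_dev <= 0.01), label = paste(tab, "LR+"))
    expect_true(all(rec$lr_neg_dev <= 0.01), label = paste(tab, "LR-"))
  }
  rec4 <- recompute_likelihood_ratios(reference_table("sos_panel"), digits = 4)
  expect_true(all(rec4$lr_pos_dev <= 1e-4 + 1e-9))
  expect_true(all(rec4$lr_neg_dev <= 1e-4 + 1e-9))
})

test_that("best cut-off maximises accuracy with Youden then smallest-threshold ties", {
  expect_equal(best_cutoff(c(2, 0, 1, -1), c(1, 1, 0, 0)), -0.5)
  cut <- best_cutoff(c(1, 2, 3, -1, -2, 0), rep(c(1, 0), each = 3))
  expect_equal(cut, 0.5)
  d <- diagnostics_at(c(1, 2, 3, -1, -2, 0), rep(c(1, 0), each = 3), cut)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  # constant scores: accuracy equals majority fraction at an infinite end
  cc <- best_cutoff(rep(1, 6), c(1, 1, 1, 1, 0, 0))
  dcc <- diagnostics_at(rep(1, 6), c(1, 1, 1, 1, 0, 0), cc)
  expect_equal((dcc$tp + dcc$tn) / 6, 4 / 6)
})

test_that("diagnostics_at reproduces confusion arithmetic and conventions", {
  scores <- c(rep(1, 48), rep(-1, 2), rep(-1, 28), rep(1, 2))
  labels <- rep(c(1, 0), c(50, 30))
  d <- diagnostics_at(scores, labels, 0)
  expect_equal(c(d$tp, d$fn, d$tn, d$fp), c(48, 2, 28, 2))
  expect_equal(d$sensitivity, 0.96)
  expect_equal(d$specificity, 28 / 30)
  expect_equal(d$ppv, 0.96)
  expect_equal(d$npv, 28 / 30)
  expect_equal(d$lr_pos, 0.96 / (2 / 30), tolerance = 1e-12)
  expect_equal(round(d$lr_pos, 2), 14.40)
  expect_equal(round(d$lr_neg, 4), 0.0429)
  # conservation at any cutoff
  for (cut in c(-2, -1, 0, 0.5, 2)) {
    di <- diagnostics_at(scores, labels, cut)
    expect_equal(di$tp + di$fn, 50)
    expect_equal(di$tn + di$fp, 30)
    if (!is.nan(di$specificity) && di$specificity < 1)
      expect_equal(di$lr_pos * (1 - di$specificity), di$sensitivity,
                   tolerance = 1e-12)
  }
  # boundary cutoffs: undefined predictive values are flagged NaN
  lo <- diagnostics_at(scores, labels, -10)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_true(is.nan(lo$npv) && lo$undefined[["npv"]])
  hi <- diagnostics_at(scores, labels, 10)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  # Clopper-Pearson CI agrees with binom.test
  expect_equal(d$sensitivity_ci,
               as.numeric(binom.test(48, 50)$conf.int), tolerance = 1e-12)
})

test_that("target-seeking cut-offs maximise the complementary yield", {
  scores <- c(rnorm(30, 3, 0.2), rnorm(30, 0, 0.2))
  labels <- rep(c(1, 0), each = 30)
  cut <- threshold_for_target(scores, labels, "ppv", 0.95)
  d <- diagnostics_at(scores, labels, cut)
  expect_gte(d$ppv, 0.95)
  expect_equal(d$sensitivity, 1)

  expect_true(is.na(threshold_for_target(rep(1, 20), rep(c(1, 0), 10),
                                         "ppv", 0.99)))

  # exhaustive-scan oracle on a small overlapping case
  s <- c(3, 2, 1, 2, 1, 0); lab <- rep(c(1, 0), each = 3)
  cut2 <- threshold_for_target(s, lab, "npv", 0.66)
  all_thr <- c(-Inf, sort(unique(s))[-1] - 0.5, Inf)
  cand <- Filter(function(t) {
    d <- diagnostics_at(s, lab, t); !is.nan(d$npv) && d$npv >= 0.66
  }, all_thr)
  best_spec <- max(vapply(cand, function(t)
    diagnostics_at(s, lab, t)$specificity, 0))
  d2 <- diagnostics_at(s, lab, cut2)
  expect_gte(d2$npv, 0.66)
  expect_equal(d2$specificity, best_spec)
})

test_that("panel evaluation aborts with named genes when entities are missing", {
  co <- preprocess_cohort(generate_cohort(tiny_design(n_probes = 30, seed = 12),
                                          ioi_effects()[1:2]))
  miss <- evaluate_panel(panel_def("CD177+NOTHERE"), co,
                         positive = c("SIRS", "ABDM", "PLMN"), negative = "CNTRL")
  expect_s3_class(miss, "panel_eval_missing")
  expect_equal(miss$missing_genes, "NOTHERE")
  expect_null(miss$roc)

  ok1 <- evaluate_panel(panel_def("CD177+FAM20A"), co,
                        positive = c("SIRS", "ABDM", "PLMN"), negative = "CNTRL")
  ok2 <- evaluate_panel(panel_def("CD177+FAM20A"), co,
                        positive = c("SIRS", "ABDM", "PLMN"), negative = "CNTRL")
  expect_gte(ok1$roc$auc, 0.95)
  expect_identical(ok1$roc, ok2$roc)
  expect_identical(ok1$best$cutoff, ok2$best$cutoff)
})

test_that("probe collapse policies resolve duplicate probes", {
  d <- tiny_design(n_probes = 12, probes_per_gene = 2L, seed = 3)
  co <- preprocess_cohort(generate_cohort(d, list(
    planted_effect("CD177", c("SIRS", "ABDM", "PLMN"), 20))))
  for (policy in c("best_auc", "mean", "first")) {
    ev <- evaluate_panel(panel_def("CD177", probe_policy = policy), co,
                         positive = c("SIRS", "ABDM", "PLMN"), negative = "CNTRL")
    expect_gte(ev$roc$auc, 0.9)
  }
})

test_that("marker correlations use mid-rank Spearman with unit diagonal", {
  co <- generate_cohort(tiny_design(n_probes = 20, seed = 15), list(
    planted_effect("CD177", c("SIRS", "ABDM", "PLMN"), 20),
    planted_effect("FAM20A", c("SIRS", "ABDM", "PLMN"), 20)))
  cm <- correlate_markers(co, c("CD177", "FAM20A", "BG00001"))
  expect_equal(diag(cm), c(CD177 = 1, FAM20A = 1, BG00001 = 1))
  expect_equal(cm, t(cm))
  expect_gt(cm["CD177", "FAM20A"], 0.5)  # shared group structure
  # worked rank example and exact symmetries via the same engine
  expect_equal(cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman"), 0.8)
  v <- co$expr["CD177", 1:10]
  expect_equal(suppressWarnings(cor(v, -v, method = "spearman")), -1)
})
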