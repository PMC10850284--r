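test_that("generated cohorts honour the design and are deterministic", {
  d <- cohort_design(n_probes = 80, seed = 11)
  co <- generate_cohort(d, ioi_effects()[1:2])
  d1 <- subset(co$annotation, timepoint == "D1")
  expect_equal(as.vector(table(d1$group)[c("CNTRL", "SIRS", "ABDM", "PLMN")]),
               c(30L, 42L, 59L, 84L))
  co2 <- generate_cohort(d, ioi_effects()[1:2])
  expect_identical(co$expr, co2$expr)
  expect_identical(co$annotation, co2$annotation)
})

test_that("attrition is monotone and controls are admission-only", {
  co <- generate_cohort(tiny_design(seed = 4))
  tp <- co$design$timepoints
  present <- with(co$annotation,
                  table(factor(subject_id), factor(timepoint, levels = tp)) > 0)
  for (j in seq_along(tp)[-1])
    expect_true(all(present[, j - 1][present[, j]]))
  ctrl <- subset(co$annotation, group == "CNTRL")
  expect_true(all(ctrl$timepoint == "D1"))
})

test_that("planted effects are recovered at the stated scale", {
  # FC +20, all-disease effect: realized Day1 FC within a 2-SE band of 20
  # (SE of the mean log2 difference = 0.5 * sqrt(1/30 + 1/126) ~ 0.102)
  hits <- vapply(1:100, function(s) {
    d <- cohort_design(n_probes = 20, seed = s)
    co <- generate_cohort(d, list(planted_effect("GENE1", c("SIRS", "ABDM", "PLMN"), 20)))
    fc <- realized_fold_change(co, "GENE1", c("SIRS", "ABDM", "PLMN"), "CNTRL")
    fc >= 17 && fc <= 23
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("zero-noise cohorts reproduce planted fold changes exactly", {
  d <- tiny_design(n_probes = 10, probe_noise_sd = 0)
  co <- generate_cohort(d, list(planted_effect("GENE1", c("SIRS", "ABDM", "PLMN"), 32)))
  expect_equal(realized_fold_change(co, "GENE1", c("SIRS", "ABDM", "PLMN"), "CNTRL"), 32)
  expect_equal(realized_fold_change(co, "BG00001", "SIRS", "CNTRL"), 1.0)
})

test_that("down-regulated effects keep their sign under noise", {
  signs <- vapply(1:200, function(s) {
    d <- cohort_design(n_probes = 5, seed = s)
    co <- generate_cohort(d, list(planted_effect("GENE1", c("SIRS", "ABDM", "PLMN"), -7.09)))
    realized_fold_change(co, "GENE1", c("SIRS", "ABDM", "PLMN"), "CNTRL") < 0
  }, TRUE)
  expect_gte(mean(signs), 0.99)
})

test_that("temporal profile scales the shift toward discharge", {
  d <- cohort_design(group_sizes = c(CNTRL = 5L, SIRS = 40L),
                     n_probes = 4, probe_noise_sd = 0, dropout_prob = 0,
                     dropout_prob_dns = 0, survival_prob = c(CNTRL = 1, SIRS = 1),
                     seed = 2)
  co <- generate_cohort(d, list(planted_effect("GENE1", "SIRS", 16)))
  ann <- co$annotation
  shift_at <- function(tp) {
    sirs <- ann$sample_id[ann$group == "SIRS" & ann$timepoint == tp]
    base <- mean(co$expr["BG00001", ])  # untouched probe as sanity anchor
    mean(co$expr["GENE1", sirs]) - mean(co$expr["GENE1",
      ann$sample_id[ann$group == "CNTRL"]])
  }
  expect_equal(shift_at("D1"), 4 * 1.0)
  expect_equal(shift_at("D2"), 4 * 0.9)
  expect_equal(shift_at("D5"), 4 * 0.6)
  expect_equal(shift_at("DC"), 4 * 0.3)
})

test_that("multiple probes per planted gene share the effect", {
  d <- tiny_design(n_probes = 12, probes_per_gene = 3L, probe_noise_sd = 0)
  co <- generate_cohort(d, list(planted_effect("CD177", c("SIRS", "ABDM", "PLMN"), 8)))
  expect_equal(sum(co$probes$gene == "CD177"), 3L)
  expect_equal(realized_fold_change(co, "CD177", c("SIRS", "ABDM", "PLMN"), "CNTRL"), 8)
})

test_that("invalid designs and effects are rejected", {
  expect_error(generate_cohort(tiny_design(n_probes = 1),
                               list(planted_effect("A", "SIRS", 2),
                                    planted_effect("B", "SIRS", 2))),
               "n_probes")
  expect_error(generate_cohort(tiny_design(),
                               list(planted_effect("A", "NOSUCH", 2))),
               "unknown group")
  expect_error(planted_effect("A", "SIRS", 0.5))
})

test_that("clinical simulation matches median/IQR targets", {
  tg <- data.frame(group = "ABDM", variable = "CRP",
                   median = 202, q1 = 108, q3 = 300, integer = FALSE)
  d <- cohort_design(group_sizes = c(CNTRL = 5L, ABDM = 141L), seed = 1)
  meds_ok <- vapply(1:100, function(s) {
    cl <- simulate_clinical(d, tg, seed = s)
    m <- median(cl$value[cl$variable == "CRP"])
    m >= 108 && m <= 300
  }, TRUE)
  expect_gte(mean(meds_ok), 0.99)

  # quantile-matching rule against a numeric quantile-solver oracle
  par <- lognormal_from_iqr(100, 50, 200)
  expect_equal(unname(par["meanlog"]), log(100))
  expect_equal(unname(exp(par["meanlog"])), 100)
  expect_equal(qlnorm(0.75, par["meanlog"], par["sdlog"]) /
                 qlnorm(0.25, par["meanlog"], par["sdlog"]), 200 / 50,
               tolerance = 1e-10)
  oracle_sd <- uniroot(function(s) qlnorm(0.75, log(100), s) -
                         qlnorm(0.25, log(100), s) * 4, c(1e-6, 10),
                       tol = 1e-12)$root
  expect_equal(unname(par["sdlog"]), oracle_sd, tolerance = 1e-6)

  # collapsed IQR -> constant values; inverted IQR -> error
  tg0 <- data.frame(group = "ABDM", variable = "SOFA",
                    median = 17, q1 = 17, q3 = 17, integer = TRUE)
  cl0 <- simulate_clinical(d, tg0, seed = 3)
  expect_true(all(cl0$value == 17))
  expect_error(simulate_clinical(d, transform(tg, q1 = 400)), "inverted")
})

test_that("cohort TSV round trip is lossless to numeric precision", {
  co <- generate_cohort(tiny_design(n_probes = 15, seed = 9), ioi_effects()[1])
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$expr, co$expr, tolerance = 1e-10)
  expect_equal(back$annotation$sample_id, co$annotation$sample_id)
  expect_equal(back$probes$gene, co$probes$gene)
})
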