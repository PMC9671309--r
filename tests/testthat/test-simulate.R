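test_that("generator is reproducible and respects instrument ranges", {
  cfg <- cohort_config(n_per_group = c(BD = 5, HC = 5, BPD = 5), weeks = 30)
  c1 <- generate_cohort(cfg, seed = 8)
  c2 <- generate_cohort(cfg, seed = 8)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  rng <- instrument_ranges()
  for (s in c1) {
    for (ch in colnames(s$scores)) {
      expect_true(all(s$scores[, ch] >= 0 & s$scores[, ch] <= rng[[ch]]))
    }
  }
  expect_identical(as.data.frame(simulate_cohort(cfg, seed = 8)),
                   as.data.frame(simulate_cohort(cfg, seed = 8)))
})

test_that("zero innovation yields constant healthy-control scores", {
  dyn <- moodsig:::.group_dynamics_defaults()
  dyn$HC$innovation_sd[] <- 0
  cfg <- cohort_config(n_per_group = c(BD = 1, HC = 3, BPD = 1),
                       weeks = 20, dynamics = dyn)
  coh <- generate_cohort(cfg, seed = 9)
  dx <- vapply(coh, `[[`, character(1), "diagnosis")
  for (s in coh[dx == "HC"]) {
    expect_equal(unname(apply(s$scores, 2, function(v) length(unique(v)))),
                 rep(1, 4))
  }
})

test_that("a zero episode hazard makes bipolar dynamics match its baseline process", {
  dyn <- moodsig:::.group_dynamics_defaults()
  dyn$BD$episodes$hazard <- 0
  # an HC group given the BD baseline parameters, for comparison
  dyn$HC <- dyn$BD
  dyn$HC$episodes <- NULL
  cfg <- cohort_config(n_per_group = c(BD = 50, HC = 50, BPD = 1),
                       weeks = 30, dynamics = dyn)
  coh <- generate_cohort(cfg, seed = 10)
  dx <- vapply(coh, `[[`, character(1), "diagnosis")
  qids_mean <- function(g) mean(vapply(coh[dx == g], function(s)
    mean(s$scores[, "QIDS"]), numeric(1)))
  qids_sd <- stats::sd(vapply(coh[dx %in% c("BD", "HC")], function(s)
    mean(s$scores[, "QIDS"]), numeric(1)))
  expect_lt(abs(qids_mean("BD") - qids_mean("HC")), 3 * qids_sd)
})

test_that("missingness injection hits its configured rates", {
  cfg <- cohort_config(n_per_group = c(BD = 30, HC = 30, BPD = 30),
                       weeks = 52,
                       missing_base = c(BD = 0.25, HC = 0.05, BPD = 0.40))
  coh <- simulate_cohort(cfg, seed = 12)
  mr <- missing_rate(coh)
  expect_lt(abs(mr[["HC"]] - 0.05), 0.03)
  expect_lt(abs(mr[["BD"]] - 0.25), 0.03)
  expect_lt(abs(mr[["BPD"]] - 0.40), 0.03)
  # calibration improves (or stays tight) as the cohort grows
  cfg_small <- cohort_config(n_per_group = c(BD = 6, HC = 6, BPD = 6),
                             weeks = 20,
                             missing_base = c(BD = 0.25, HC = 0.05,
                                              BPD = 0.40))
  mr_small <- missing_rate(simulate_cohort(cfg_small, seed = 12))
  expect_lt(abs(mr_small[["BPD"]] - 0.40), 0.10)
  # extremes
  cfg0 <- cohort_config(n_per_group = c(BD = 2, HC = 2, BPD = 2), weeks = 12,
                        missing_base = c(BD = 0, HC = 0, BPD = 0))
  expect_equal(unname(missing_rate(simulate_cohort(cfg0, seed = 1))),
               rep(0, 3))
  cfg1 <- cohort_config(n_per_group = c(BD = 2, HC = 2, BPD = 2), weeks = 12,
                        missing_base = c(BD = 1, HC = 1, BPD = 1))
  coh1 <- simulate_cohort(cfg1, seed = 1)
  expect_equal(unname(missing_rate(coh1)), rep(1, 3))
  # a fully missing channel is rejected downstream with a named error
  expect_error(encode_missing(coh1[[1]]), "entirely missing")
})

test_that("MNAR coupling raises missingness in high-distress weeks", {
  cfg <- cohort_config(n_per_group = c(BD = 0, HC = 0, BPD = 40), weeks = 52,
                       missing_base = c(BD = 0.2, HC = 0.2, BPD = 0.2),
                       mnar_coef = 2)
  full <- generate_cohort(cfg, seed = 14)
  miss <- inject_missing(full, cfg, seed = 15)
  hi <- lo <- 0
  hin <- lon <- 0
  for (i in seq_along(full)) {
    z <- attr(full[[i]], "distress")
    m <- miss[[i]]$scores[, 1] == -1
    hi <- hi + sum(m[z > 0]); hin <- hin + sum(z > 0)
    lo <- lo + sum(m[z <= 0]); lon <- lon + sum(z <= 0)
  }
  expect_gt(hi / hin, lo / lon + 0.1)
})

test_that("with identical dynamics the score channels carry no group signal", {
  cfg <- cohort_config("missingness-only", weeks = 52)
  coh <- generate_cohort(cfg, seed = 16)   # before missingness
  dx <- vapply(coh, `[[`, character(1), "diagnosis")
  m <- vapply(coh, function(s) mean(s$scores[, "QIDS"]), numeric(1))
  fit <- stats::oneway.test(m ~ factor(dx))
  expect_gt(fit$p.value, 0.01)
})
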