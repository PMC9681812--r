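test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_subjects = 20, seed = 31, panels = "iSway2",
                           visit_months = c(0L, 12L))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$subjects, s2$cohort$subjects)
  expect_identical(s1$cohort$clinical, s2$cohort$clinical)
  expect_identical(s1$cohort$features, s2$cohort$features)
  expect_identical(s1$truth$latent_rate, s2$truth$latent_rate)
  # and the written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1$cohort, d1); write_cohort(s2$cohort, d2)
  for (f in c("demographics.csv", "clinical.csv", "features.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulate_cohort(simulation_config(n_subjects = 20, seed = 32,
                                          panels = "iSway2",
                                          visit_months = c(0L, 12L)))
  expect_false(identical(s3$cohort$clinical, s1$cohort$clinical))
})

test_that("generated panels carry the canonical parameter counts per trial", {
  sim <- sim_small(n = 4, seed = 37, panels = c("iSway1", "iSway2", "iTUG"),
                   months = c(0L, 24L))
  ft <- sim$cohort$features
  counts <- with(ft[ft$subject_id == "S0001" & ft$nominal_month == 0L &
                      ft$trial_index == 1L, ], table(panel))
  expect_equal(unname(counts[c("iTUG", "iSway1", "iSway2")]),
               c(96L, 46L, 33L), ignore_attr = TRUE)
  # three trials per panel per visit
  expect_setequal(unique(ft$trial_index), 1:3)
})

test_that("requested cohort size and schedule are honoured", {
  sim <- simulate_cohort(simulation_config(n_subjects = 230, seed = 41,
                                           panels = "iSway2",
                                           visit_months = c(0L, 6L, 12L)))
  expect_equal(nrow(sim$cohort$subjects), 230)
  expect_setequal(unique(sim$cohort$clinical$nominal_month), c(0L, 6L, 12L))
  expect_length(sim$truth$latent_rate, 230)
})

test_that("annual-only instruments are absent at months 6 and 18", {
  sim <- sim_small(n = 15, seed = 43, months = c(0L, 6L, 12L, 18L, 24L))
  cl <- sim$cohort$clinical
  semi <- cl$nominal_month %in% c(6L, 18L)
  expect_true(all(is.na(cl$moca[semi])))
  expect_true(all(is.na(cl$se[semi])))
  expect_true(all(is.na(cl$pdq39_mobility[semi])))
  expect_true(all(!is.na(cl$moca[!semi])))
  expect_true(all(!is.na(cl$updrs_total)))
})

test_that("null-signal features are uncorrelated with the latent rate", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 800, seed = 47, signal_strength = 0, panels = "iSway2",
    visit_months = 0L, visit_attrition = 0, panel_missingness = 0))
  X <- build_feature_matrix(sim$cohort, sim$cohort$subjects$subject_id,
                            "iSway2")
  r <- sim$truth$latent_rate[rownames(X)]
  cors <- apply(X, 2L, cor, y = r)
  expect_lt(max(abs(cors)), 0.1)
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("signal strength sets the feature-rate correlation direction and size", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 400, seed = 53, signal_strength = 0.8, n_informative = 6,
    panels = "iSway2", visit_months = 0L, visit_attrition = 0,
    panel_missingness = 0, noise_scale = 0))
  X <- build_feature_matrix(sim$cohort, sim$cohort$subjects$subject_id,
                            "iSway2")
  r <- sim$truth$latent_rate[rownames(X)]
  inf <- sim$truth$informative$iSway2
  cors <- vapply(seq_len(nrow(inf)), function(i) {
    cor(X[, inf$parameter[i]], r)
  }, numeric(1))
  expect_equal(cors, sign(inf$loading) * 0.8, tolerance = 0.1)
  other <- setdiff(colnames(X), inf$parameter)
  expect_lt(max(abs(apply(X[, other], 2L, cor, y = r))), 0.2)
})

test_that("baseline score distributions match their calibration targets", {
  sim <- simulate_cohort(simulation_config(n_subjects = 400, seed = 59,
                                           panels = "iSway2",
                                           visit_months = 0L))
  base <- gaitprog:::baseline_clinical(sim$cohort)
  tg <- gaitprog:::baseline_targets()
  for (inst in c("updrs1", "updrs2", "updrs3", "updrs4", "ledd", "se",
                 "moca", "pdq39_mobility", "hy")) {
    t <- tg[tg$instrument == inst, ]
    med <- median(base[[inst]])
    # within 10% of the target median, with an absolute floor of one
    # discretization step for targets at or near zero
    tol <- max(0.1 * abs(t$median), t$step)
    expect_lt(abs(med - t$median), tol + 1e-9)
  }
  # instrument hard scales are respected even with measurement noise
  expect_true(all(base$se >= 0 & base$se <= 1))
  expect_true(all(base$moca >= 0 & base$moca <= 31))
  expect_true(all(base$hy >= 1 & base$hy <= 5))
  expect_equal(mean(sim$cohort$subjects$sex == "male"), 0.6087,
               tolerance = 0.12)
})

test_that("LEDD change is zero-inflated: many exact zero changes early", {
  sim <- sim_small(n = 120, seed = 61, months = c(0L, 6L, 12L, 24L))
  oc <- compute_outcomes(sim$cohort, 6L, "ledd")
  expect_gt(mean(oc$annual_rate == 0), 0.4)
  expect_true(all(oc$annual_rate >= 0))
})

test_that("pipeline estimates recover true slopes when noise is absent", {
  sim <- sim_small(n = 50, seed = 67, noise = 0, months = c(0L, 24L))
  rec <- recover_truth(sim$cohort, sim$truth, "updrs_total", 24L)
  # integer rounding of scores is the only distortion left
  expect_gt(rec$rank_correlation, 0.97)
  est <- compute_outcomes(sim$cohort, 24L, "updrs_total")
  truth <- with(sim$truth$outcome_slopes,
                setNames(updrs_total, subject_id))[est$subject_id]
  # annualized change equals the true slope up to score discretization
  # (four parts, each rounded at two visits, over two years)
  expect_lt(max(abs(est$annual_rate - truth)), 2.01)
  expect_error(recover_truth(sim$cohort, sim_small(n = 8, seed = 1)$truth),
               class = "gaitprog_domain_error")
})
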