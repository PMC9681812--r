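test_that("LEDD sums dose x factor, with Rytary 0.7 and Duopa 0.97", {
  expect_equal(compute_ledd(c(rytary = 435)), 304.5)
  expect_equal(compute_ledd(c(duopa = 1000)), 970)
  expect_equal(compute_ledd(numeric(0)), 0)
  expect_equal(compute_ledd(c(levodopa = 300, rytary = 100)), 300 + 70)
  expect_error(compute_ledd(c(levodopa = -10)),
               class = "gaitprog_domain_error")
  expect_error(compute_ledd(c(unknown_drug = 100)),
               class = "gaitprog_domain_error")
})

test_that("annualized change is (horizon - baseline) / years", {
  expect_equal(annualized_change(36, 38, 0.5), 4)
  expect_equal(annualized_change(10, 10, 1.5), 0)
  expect_equal(annualized_change(600, 839, 2), 119.5)
  expect_error(annualized_change(1, 2, 0), class = "gaitprog_domain_error")
  expect_error(annualized_change(1, 2, -1), class = "gaitprog_domain_error")
  # linear in the horizon value, antisymmetric under swapping the values
  b <- 3; y <- 1.5
  for (h in c(-2, 0, 7)) {
    expect_equal(annualized_change(b, h, y), (h - b) / y)
    expect_equal(annualized_change(h, b, y), -annualized_change(b, h, y))
  }
  expect_true(is.na(annualized_change(NA, 5, 1)))
})

test_that("GCO reference has the stated means, SDs and signs", {
  co <- mini_cohort(n = 2)
  # force component values {0, 2} etc. at baseline for a hand-checkable
  # reference (every component needs non-zero spread)
  two <- co$clinical$subject_id == "M02"
  co$clinical$updrs1 <- ifelse(two, 2, 0)
  co$clinical$updrs2 <- ifelse(two, 8, 6)
  co$clinical$se <- ifelse(two, 1, 0.8)
  co$clinical$moca <- ifelse(two, 28, 26)
  co$clinical$updrs_total <- with(co$clinical, updrs1 + updrs2 + updrs3 + updrs4)
  co <- pd_cohort(co$subjects, co$clinical, co$features)
  ref <- fit_gco_reference(co)
  expect_equal(ref$mean[ref$component == "updrs1"], 1)
  expect_equal(ref$sd[ref$component == "updrs1"], sqrt(2))
  expect_identical(ref$sign, c(1, 1, 1, -1, -1))
  # a single subject cannot define a reference
  one <- pd_cohort(co$subjects[1, ],
                   co$clinical[co$clinical$subject_id == "M01", ],
                   co$features[co$features$subject_id == "M01", ])
  expect_error(fit_gco_reference(one), class = "gaitprog_domain_error")
})

test_that("a zero-SD component yields a degenerate-reference error", {
  co <- mini_cohort(n = 4)  # all subjects share updrs1 = 4 at baseline
  expect_error(fit_gco_reference(co),
               class = "gaitprog_degenerate_reference_error")
})

test_that("GCO evaluates its defining average of signed z-scores", {
  ref <- structure(data.frame(
    component = c("updrs1", "updrs2", "updrs3", "se", "moca"),
    mean = c(8, 8, 17, 0.9, 27), sd = c(4, 5, 10, 0.1, 2),
    sign = c(1, 1, 1, -1, -1)), class = c("gco_reference", "data.frame"))
  at_mean <- list(updrs1 = 8, updrs2 = 8, updrs3 = 17, se = 0.9, moca = 27)
  expect_equal(compute_gco(at_mean, ref), 0)
  # every component at +1 SD: (1 + 1 + 1 - 1 - 1) / 5 = 0.2
  plus1 <- list(updrs1 = 12, updrs2 = 13, updrs3 = 27, se = 1.0, moca = 29)
  expect_equal(compute_gco(plus1, ref), 0.2)
  # monotone: UPDRS up -> GCO up; MoCA or S&E up -> GCO down
  expect_gt(compute_gco(modifyList(at_mean, list(updrs3 = 20)), ref), 0)
  expect_lt(compute_gco(modifyList(at_mean, list(moca = 29)), ref), 0)
  expect_lt(compute_gco(modifyList(at_mean, list(se = 1.0)), ref), 0)
  # equal weighting: swapping two UPDRS component values leaves GCO unchanged
  a <- modifyList(at_mean, list(updrs1 = 12, updrs2 = 8))
  b <- modifyList(at_mean, list(updrs1 = 8, updrs2 = 12))
  ref_eq <- ref; ref_eq$mean[1:2] <- 8; ref_eq$sd[1:2] <- 4
  expect_equal(compute_gco(a, ref_eq), compute_gco(b, ref_eq))
  expect_true(is.na(compute_gco(modifyList(at_mean, list(moca = NA)), ref)))
})

test_that("own-reference z-scores standardize to mean 0, SD 1", {
  sim <- sim_small(n = 60, seed = 21)
  ref <- fit_gco_reference(sim$cohort)
  base <- gaitprog:::baseline_clinical(sim$cohort)
  for (i in seq_len(nrow(ref))) {
    z <- (base[[ref$component[i]]] - ref$mean[i]) / ref$sd[i]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("follow-up groups require baseline data plus the horizon visit", {
  co <- mini_cohort(n = 3, months = c(0L, 6L))
  g <- assign_followup_groups(co)
  expect_setequal(g[["6"]], c("M01", "M02", "M03"))
  expect_length(g[["12"]], 0)
  # baseline-only subject belongs to no group
  cl <- co$clinical[co$clinical$nominal_month == 0L, ]
  co0 <- pd_cohort(co$subjects, cl, co$features)
  expect_true(all(lengths(assign_followup_groups(co0)) == 0))
  # full attendance puts a subject in all four groups
  full <- mini_cohort(n = 3, months = c(0L, 6L, 12L, 18L, 24L))
  expect_true(all(vapply(assign_followup_groups(full),
                         function(m) "M01" %in% m, logical(1))))
})

test_that("annual-only outcomes exist at 12 and 24 months only", {
  sim <- sim_small(n = 30, months = c(0L, 6L, 12L, 18L, 24L))
  oc <- compute_outcomes(sim$cohort)
  annual <- oc[oc$outcome_name %in% c("moca", "se", "pdq39_mobility", "gco"), ]
  expect_true(all(annual$horizon_months %in% c(12L, 24L)))
  semi <- oc[oc$outcome_name %in% c("updrs_total", "ledd"), ]
  expect_setequal(unique(semi$horizon_months), c(6L, 12L, 18L, 24L))
})

test_that("median change summaries use median and interpolated quartiles", {
  oc <- data.frame(subject_id = c("a", "b", "c"), outcome_name = "updrs_total",
                   horizon_months = 24L, annual_rate = c(-1, 0, 1))
  s <- summarize_median_change(oc, "updrs_total", 24L)
  expect_equal(unname(s[c("median", "q1", "q3")]), c(0, -0.5, 0.5))
  single <- oc[2, ]
  single$annual_rate <- 5
  s1 <- summarize_median_change(single, "updrs_total", 24L)
  expect_equal(unname(s1[c("median", "q1", "q3")]), c(5, 5, 5))
  expect_error(summarize_median_change(oc, "ledd", 24L),
               class = "gaitprog_domain_error")
  # table layout: annual-only cells are NA at 6 and 18 months
  tab <- median_change_table(oc)
  expect_true(is.na(tab$median[tab$outcome_name == "moca" &
                                 tab$horizon_months == 6]))
  expect_equal(tab$median[tab$outcome_name == "updrs_total" &
                            tab$horizon_months == 24], 0)
})
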