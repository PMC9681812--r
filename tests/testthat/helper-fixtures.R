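# Fixtures built in code: a small hand-written cohort with known visit
# structure, and an independent brute-force oracle for the gamma statistic.

empty_clinical_row <- function(subject_id, nominal_month,
                               elapsed_years = NA_real_) {
  data.frame(subject_id = subject_id, nominal_month = nominal_month,
             elapsed_years = elapsed_years,
             updrs1 = NA_real_, updrs2 = NA_real_, updrs3 = NA_real_,
             updrs4 = NA_real_, updrs_total = NA_real_, hy = NA_real_,
             ledd = NA_real_, se = NA_real_, moca = NA_real_,
             pdq39_mobility = NA_real_, hama = NA_real_, hamd = NA_real_,
             epworth = NA_real_, upsit = NA_real_)
}

clinical_row <- function(subject_id, nominal_month, updrs = c(4, 6, 15, 1),
                         ledd = 300, se = 0.9, moca = 27, pdq39 = 5,
                         elapsed_years = NA_real_) {
  row <- empty_clinical_row(subject_id, nominal_month, elapsed_years)
  row$updrs1 <- updrs[1]; row$updrs2 <- updrs[2]
  row$updrs3 <- updrs[3]; row$updrs4 <- updrs[4]
  row$updrs_total <- sum(updrs)
  row$hy <- 2; row$ledd <- ledd
  row$se <- se; row$moca <- moca; row$pdq39_mobility <- pdq39
  row
}

# trials for one (subject, month, panel): value = base + trial offset
feature_trials <- function(subject_id, nominal_month, panel, base = 0,
                           trial_offsets = c(0, 0.5, -0.5)) {
  params <- panel_parameters(panel)
  do.call(rbind, lapply(seq_along(trial_offsets), function(tr) {
    data.frame(subject_id = subject_id, nominal_month = nominal_month,
               panel = panel, trial_index = tr, parameter = params,
               value = base + seq_along(params) + trial_offsets[tr])
  }))
}

# n subjects, months 0 and 24 fully observed, iSway1 (+ optionally iTUG)
# features at baseline; deterministic scores so outcomes are predictable
mini_cohort <- function(n = 6, panels = "iSway1", months = c(0L, 24L)) {
  ids <- sprintf("M%02d", seq_len(n))
  subjects <- data.frame(
    subject_id = ids, sex = rep(c("male", "female"), length.out = n),
    ethnicity = "non-hispanic", age = 60 + seq_len(n),
    education_years = 16, disease_duration_years = 4)
  clinical <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(months, function(m) {
      clinical_row(ids[i], m, updrs = c(4, 6, 15 + i + m %/% 12, 1),
                   ledd = 300 + 50 * i, se = 0.9, moca = 27 - (m %/% 24),
                   pdq39 = 5 + 2.5 * i)
    }))
  }))
  features <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(panels, function(p) {
      feature_trials(ids[i], 0L, p, base = i)
    }))
  }))
  pd_cohort(subjects, clinical, features)
}

# O(n^2) brute-force pair enumeration, independent of the implementation
gamma_oracle <- function(predicted, observed) {
  n <- length(predicted)
  C <- 0L; D <- 0L; Tt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dp <- predicted[j] - predicted[i]
    do <- observed[j] - observed[i]
    if (dp == 0 || do == 0) Tt <- Tt + 1L
    else if ((dp > 0) == (do > 0)) C <- C + 1L
    else D <- D + 1L
  }
  list(C = C, D = D, T = Tt,
       gamma = if (C + D > 0) (C - D) / (C + D) else NA_real_)
}

# small default simulated cohort shared across tests
sim_small <- function(n = 40, seed = 7, signal = 0, noise = 1,
                      panels = "iSway1", months = c(0L, 12L, 24L), ...) {
  simulate_cohort(simulation_config(
    n_subjects = n, seed = seed, signal_strength = signal,
    noise_scale = noise, panels = panels, visit_months = months,
    visit_attrition = 0, panel_missingness = 0, ...))
}
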