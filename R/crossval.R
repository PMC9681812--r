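# Repeated k-fold cross-validation of ridge models scored by gamma
# concordance, for every panel x outcome x horizon cell.

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic per-replicate/fold sub-seeds below 2^31
derive_seed <- function(master, i, j = 0L) {
  ((as.numeric(master) %% 65011) * 31907 + i * 2161 + j * 101) %% 2147483629
}

#' Balanced random fold assignment
#'
#' Partitions n subjects into k folds whose sizes differ by at most one,
#' uniformly at random, reproducibly for a fixed seed.
#'
#' @param n Number of subjects (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, length n.
#' @export
make_folds <- function(n, k, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || n < k)
    stop_gaitprog("gaitprog_domain_error",
                  "need n >= k >= 2 (n = %d, k = %d)", n, k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

covariate_columns <- function(cohort, subject_ids) {
  base <- baseline_clinical(cohort)
  bi <- match(subject_ids, base$subject_id)
  si <- match(subject_ids, cohort$subjects$subject_id)
  cbind(
    cov_updrs_total = base$updrs_total[bi],
    cov_ledd = base$ledd[bi],
    cov_age = cohort$subjects$age[si],
    cov_sex_male = as.numeric(cohort$subjects$sex[si] == "male"),
    cov_disease_duration = cohort$subjects$disease_duration_years[si]
  )
}

# per-subject GCO component values at baseline and horizon, for
# fold-local recomputation of gco rates against a training-only reference
gco_cell_data <- function(cohort, members, horizon, use_elapsed = FALSE) {
  bm <- baseline_months(cohort)
  cl <- cohort$clinical
  key <- paste(cl$subject_id, cl$nominal_month)
  b_rows <- cl[match(paste(members, bm[members]), key), , drop = FALSE]
  h_rows <- cl[match(paste(members, bm[members] + horizon), key), , drop = FALSE]
  ok <- stats::complete.cases(b_rows[GCO_COMPONENTS]) &
    stats::complete.cases(h_rows[GCO_COMPONENTS])
  years <- if (use_elapsed) {
    ey <- function(r) ifelse(is.na(r$elapsed_years), r$nominal_month / 12,
                             r$elapsed_years)
    ey(h_rows) - ey(b_rows)
  } else rep(horizon / 12, length(members))
  list(members = members[ok], b = b_rows[ok, , drop = FALSE],
       h = h_rows[ok, , drop = FALSE], years = years[ok])
}

gco_rates_for <- function(cell, ids, ref) {
  i <- match(ids, cell$members)
  annualized_change(compute_gco(cell$b[i, ], ref),
                    compute_gco(cell$h[i, ], ref), cell$years[i])
}

#' Cross-validated accuracy for one panel x outcome x horizon cell
#'
#' Runs the full evaluation protocol for a single cell of the accuracy
#' grid: subjects in the horizon's follow-up group with complete baseline
#' features for the panel configuration and a defined outcome are split
#' into k folds; for every fold, feature scaling is learned on the
#' training rows, the ridge penalty is selected by inner cross-validation
#' on the training rows, the model is fitted, and accuracy (percent
#' concordance, [gamma_statistic()]) is computed in-sample (fitted vs
#' observed on training rows) and out-of-sample (predicted vs observed on
#' the held-out rows). For the GCO outcome the z-score reference is also
#' refit on the training fold's baselines, so nothing about the held-out
#' subjects influences the model. The fold loop repeats for the requested
#' number of replicates; reported means and SDs are over all fold-level
#' evaluations.
#'
#' @param cohort A [pd_cohort()].
#' @param panel_config One of [panel_configs()].
#' @param outcome_name One of the six progression outcomes.
#' @param horizon_months 6, 12, 18 or 24; annual-only outcomes (MoCA,
#'   PDQ-39, S&E, GCO) are defined at 12 and 24 only.
#' @param k Folds per replicate (default 10: a 90/10 train/test split).
#' @param replicates Replicates of the full k-fold partition (scheme
#'   `"repeated-kfold"`), or random 90/10 splits (`"monte-carlo"`).
#' @param seed Master seed; all randomness (fold draws, inner-CV folds)
#'   derives from it deterministically.
#' @param scheme Cross-validation scheme, see `replicates`.
#' @param lambda_grid Candidate ridge penalties for the inner selection.
#' @param k_inner Inner folds for penalty selection.
#' @param covariates Append baseline covariate columns (UPDRS total, LEDD,
#'   age, sex, disease duration) to the feature matrix, penalized like any
#'   other column (default `TRUE`).
#' @param use_elapsed Annualize by recorded elapsed time instead of the
#'   nominal horizon.
#' @param details Also return per-evaluation records (fold assignments,
#'   selected penalties, scaling statistics) for inspection.
#' @return One-row data frame of class `accuracy_summary`: `panel_config`,
#'   `outcome_name`, `horizon_months`, `n_subjects`, `in_mean`, `in_sd`,
#'   `out_mean`, `out_sd`, `n_evaluations`, `n_skipped`. With
#'   `details = TRUE`, a list with elements `summary` and `evaluations`.
#' @export
evaluate_cell <- function(cohort, panel_config, outcome_name, horizon_months,
                          k = 10L, replicates = 100L, seed = 1L,
                          scheme = c("repeated-kfold", "monte-carlo"),
                          lambda_grid = gaitprog::lambda_grid(),
                          k_inner = 5L, covariates = TRUE,
                          use_elapsed = FALSE, details = FALSE) {
  scheme <- match.arg(scheme)
  outcome_name <- match.arg(outcome_name, OUTCOME_NAMES)
  if (outcome_name %in% ANNUAL_ONLY_OUTCOMES &&
      !horizon_months %in% c(12L, 24L))
    stop_gaitprog("gaitprog_unavailable_error",
                  "%s is an annual instrument: no %d-month outcome",
                  outcome_name, horizon_months)

  group <- assign_followup_groups(cohort, horizon_months)[[1L]]
  if (!length(group))
    stop_gaitprog("gaitprog_unavailable_error",
                  "no subjects in the %d-month follow-up group", horizon_months)
  X <- suppressWarnings(build_feature_matrix(cohort, group, panel_config))

  gco_cell <- NULL
  if (outcome_name == "gco") {
    gco_cell <- gco_cell_data(cohort, group, horizon_months, use_elapsed)
    eligible <- gco_cell$members
    rates <- NULL
  } else {
    oc <- compute_outcomes(cohort, horizon_months, outcome_name,
                           use_elapsed = use_elapsed)
    rates <- stats::setNames(oc$annual_rate, oc$subject_id)
    eligible <- names(rates)
  }
  ids <- intersect(rownames(X), eligible)
  if (covariates) {
    cov <- covariate_columns(cohort, ids)
    ids <- ids[stats::complete.cases(cov)]
  }
  n <- length(ids)
  if (n < k)
    stop_gaitprog("gaitprog_unavailable_error",
                  "only %d complete-case subjects for %s / %s / %d months (need >= k = %d)",
                  n, panel_config, outcome_name, horizon_months, k)
  X <- X[ids, , drop = FALSE]
  if (covariates) X <- cbind(X, covariate_columns(cohort, ids))

  eval_one <- function(train, test, sub_seed) {
    std <- standardize(X[train, , drop = FALSE])
    Xtr <- std$matrix
    if (outcome_name == "gco") {
      ref <- fit_gco_reference(cohort, ids[train])
      ytr <- gco_rates_for(gco_cell, ids[train], ref)
      yte <- gco_rates_for(gco_cell, ids[test], ref)
    } else {
      ytr <- unname(rates[ids[train]])
      yte <- unname(rates[ids[test]])
    }
    sel <- select_penalty(Xtr, ytr, grid = lambda_grid, k_inner = k_inner,
                          seed = sub_seed)
    fit <- fit_ridge(Xtr, ytr, sel$lambda)
    Xte <- standardize(X[test, , drop = FALSE], std$stats)$matrix
    acc <- function(pred, obs) {
      tryCatch(gamma_statistic(pred, obs)$accuracy,
               gaitprog_undefined_gamma_error = function(e) NA_real_)
    }
    list(in_acc = acc(predict(fit, Xtr), ytr),
         out_acc = acc(predict(fit, Xte), yte),
         lambda = sel$lambda,
         scaling_mean = std$stats$mean, train = train)
  }

  evals <- list()
  for (r in seq_len(replicates)) {
    if (scheme == "repeated-kfold") {
      folds <- make_folds(n, k, derive_seed(seed, r))
      for (f in seq_len(k)) {
        e <- eval_one(which(folds != f), which(folds == f),
                      derive_seed(seed, r, f))
        e$replicate <- r; e$fold <- f
        evals[[length(evals) + 1L]] <- e
      }
    } else {
      test <- with_seed(derive_seed(seed, r),
                        sample(n, size = max(1L, round(n / k))))
      e <- eval_one(setdiff(seq_len(n), test), test, derive_seed(seed, r, 1L))
      e$replicate <- r; e$fold <- 1L
      evals[[length(evals) + 1L]] <- e
    }
  }

  in_acc <- vapply(evals, `[[`, numeric(1), "in_acc")
  out_acc <- vapply(evals, `[[`, numeric(1), "out_acc")
  skipped <- sum(is.na(out_acc) | is.na(in_acc))
  if (skipped)
    warning(sprintf("%d fold evaluation(s) skipped (gamma undefined: all pairs tied)",
                    skipped), call. = FALSE)
  summary <- data.frame(
    panel_config = panel_config, outcome_name = outcome_name,
    horizon_months = as.integer(horizon_months), n_subjects = n,
    in_mean = mean(in_acc, na.rm = TRUE), in_sd = stats::sd(in_acc[!is.na(in_acc)]),
    out_mean = mean(out_acc, na.rm = TRUE),
    out_sd = stats::sd(out_acc[!is.na(out_acc)]),
    n_evaluations = length(evals) - skipped, n_skipped = skipped
  )
  class(summary) <- c("accuracy_summary", "data.frame")
  if (!details) return(summary)
  list(summary = summary,
       subject_ids = ids,
       matrix = X,
       evaluations = evals)
}

#' Accuracy grid over all panels, outcomes and horizons
#'
#' Evaluates [evaluate_cell()] for every combination of panel
#' configuration, outcome and horizon, skipping combinations that are
#' undefined by design (annual-only outcomes at 6 and 18 months) and
#' marking cells without enough eligible subjects as unavailable rather
#' than aborting the run. With the full outcome set this is 5 panels x
#' (2 + 6 + 2 + 6) = 80 cells.
#'
#' @param cohort A [pd_cohort()].
#' @param panels Panel configurations to evaluate.
#' @param outcomes Outcomes to evaluate.
#' @param horizons Follow-up horizons in months.
#' @param seed Master seed; each cell receives a deterministic sub-seed.
#' @param ... Passed to [evaluate_cell()] (`k`, `replicates`, `scheme`,
#'   `lambda_grid`, `covariates`, ...).
#' @return Data frame with one row per evaluated cell (the
#'   `accuracy_summary` columns plus `available`); unavailable cells keep
#'   their identifiers with NA accuracies.
#' @export
run_grid <- function(cohort, panels = panel_configs(),
                     outcomes = OUTCOME_NAMES,
                     horizons = c(6L, 12L, 18L, 24L), seed = 1L, ...) {
  rows <- list()
  cell_i <- 0L
  for (p in panels) for (h in horizons) for (oc in outcomes) {
    if (oc %in% ANNUAL_ONLY_OUTCOMES && !h %in% c(12L, 24L)) next
    cell_i <- cell_i + 1L
    res <- tryCatch(
      evaluate_cell(cohort, p, oc, h, seed = derive_seed(seed, cell_i), ...),
      gaitprog_unavailable_error = function(e) {
        message(sprintf("cell unavailable (%s / %s / %d mo): %s",
                        p, oc, h, conditionMessage(e)))
        data.frame(panel_config = p, outcome_name = oc,
                   horizon_months = as.integer(h), n_subjects = 0L,
                   in_mean = NA_real_, in_sd = NA_real_,
                   out_mean = NA_real_, out_sd = NA_real_,
                   n_evaluations = 0L, n_skipped = 0L)
      })
    res$available <- res$n_evaluations > 0L
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape an accuracy grid into the wide report layout
#'
#' One row per panel x outcome; per horizon, four columns: in-sample and
#' out-of-sample mean accuracy with their SDs.
#'
#' @param grid Output of [run_grid()].
#' @return Wide data frame.
#' @export
format_accuracy_table <- function(grid) {
  horizons <- sort(unique(grid$horizon_months))
  keys <- unique(grid[c("panel_config", "outcome_name")])
  out <- keys
  for (h in horizons) {
    sub <- grid[grid$horizon_months == h, ]
    i <- match(paste(keys$panel_config, keys$outcome_name),
               paste(sub$panel_config, sub$outcome_name))
    for (col in c("in_mean", "in_sd", "out_mean", "out_sd"))
      out[[sprintf("m%d_%s", h, col)]] <- sub[[col]][i]
  }
  rownames(out) <- NULL
  out
}
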