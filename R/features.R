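# Per-visit aggregation of feature trials and model-ready baseline matrices.

#' Median-aggregate the trials of one visit
#'
#' Each gait/balance test is performed up to three times per visit; the
#' per-parameter median across the available trials is the value used for
#' analysis (the mean of the two for an even count, the trial itself for a
#' single trial).
#'
#' @param trials Long data frame for one visit and one panel, with columns
#'   `panel`, `trial_index`, `parameter`, `value`.
#' @return Named numeric vector of per-parameter medians, in canonical
#'   panel order, with the panel name as attribute `panel`.
#' @export
aggregate_trials <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("panel", "trial_index", "parameter", "value") %in% names(trials)))
    stop_gaitprog("gaitprog_format_error",
                  "trials must have columns panel, trial_index, parameter, value")
  if (!nrow(trials))
    stop_gaitprog("gaitprog_domain_error", "no trials to aggregate")
  panel <- unique(trials$panel)
  if (length(panel) != 1L)
    stop_gaitprog("gaitprog_domain_error",
                  "trials mix panels: %s", paste(panel, collapse = ", "))
  params <- panel_parameters(panel)
  med <- tapply(trials$value, factor(trials$parameter, levels = params),
                stats::median, na.rm = FALSE)
  out <- stats::setNames(as.numeric(med), params)
  attr(out, "panel") <- panel
  out
}

#' Baseline feature matrix for a panel configuration
#'
#' Assembles the model-ready design matrix: one row per subject, one
#' column per gait/balance parameter, values taken at each subject's
#' baseline visit after median-aggregating the trials. Combined
#' configurations (`"iSway1+iTUG"`, `"iSway2+iTUG"`) concatenate the
#' panels' columns (46 + 96 = 142 and 33 + 96 = 129). Handling of missing
#' data is complete-case: a subject missing any required panel entirely,
#' or any parameter value, is dropped with a warning. Row order follows
#' the order of `subject_ids`.
#'
#' @param cohort A [pd_cohort()].
#' @param subject_ids Subjects to include (e.g. one element of
#'   [assign_followup_groups()]).
#' @param panel_config One of [panel_configs()].
#' @return Numeric matrix with subject-id rownames, parameter colnames and
#'   attribute `panel_config`.
#' @export
build_feature_matrix <- function(cohort, subject_ids, panel_config) {
  panel_config <- match.arg(panel_config, panel_configs())
  panels <- config_panels(panel_config)
  params <- unlist(lapply(panels, panel_parameters), use.names = FALSE)
  bm <- baseline_months(cohort)
  subject_ids <- as.character(subject_ids)
  unknown <- setdiff(subject_ids, names(bm))
  if (length(unknown))
    stop_gaitprog("gaitprog_domain_error",
                  "subject(s) without a gait/balance baseline: %s",
                  paste(utils::head(unknown, 5L), collapse = ", "))

  ft <- cohort$features
  sel <- ft$subject_id %in% subject_ids & ft$panel %in% panels &
    ft$nominal_month == bm[ft$subject_id]
  ft <- ft[sel, , drop = FALSE]
  # median across trials, per (subject, parameter); equivalent to applying
  # aggregate_trials() panel-wise at each subject's baseline visit
  X <- tapply(ft$value,
              list(factor(ft$subject_id, levels = subject_ids),
                   factor(ft$parameter, levels = params)),
              stats::median)
  X <- matrix(as.numeric(X), nrow = length(subject_ids),
              dimnames = list(subject_ids, params))
  complete <- !apply(X, 1L, anyNA)
  if (any(!complete))
    warning(sprintf("dropping %d subject(s) with incomplete %s features: %s",
                    sum(!complete), panel_config,
                    paste(utils::head(subject_ids[!complete], 5L),
                          collapse = ", ")),
            call. = FALSE)
  X <- X[complete, , drop = FALSE]
  attr(X, "panel_config") <- panel_config
  X
}

#' Center and scale feature columns
#'
#' Standardizes a feature matrix to column mean 0, SD 1. When `stats` is
#' `NULL` the scaling statistics are learned from the matrix itself (the
#' training-fold contract); zero-variance columns are recorded and dropped
#' because their z-scores are undefined. When `stats` is supplied (from a
#' training fold) it is applied as-is, without re-learning, so held-out
#' columns keep their training-fold location and scale -- this is what
#' prevents information leaking from test to training data.
#'
#' @param X Numeric matrix with parameter colnames.
#' @param stats A `scaling_stats` object from a previous call, or `NULL`
#'   to learn from `X`.
#' @return List with elements `matrix` (standardized, zero-variance
#'   columns removed) and `stats` (`scaling_stats`: per-column `mean`,
#'   `sd`, the retained `columns`, and `dropped` column names).
#' @export
standardize <- function(X, stats = NULL) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(stats)) {
    mu <- colMeans(X)
    sd <- apply(X, 2L, stats::sd)
    keep <- is.finite(sd) & sd > 0
    stats <- structure(
      list(mean = mu, sd = sd, columns = colnames(X)[keep],
           dropped = colnames(X)[!keep]),
      class = "scaling_stats")
  } else {
    stopifnot(inherits(stats, "scaling_stats"))
    if (!identical(colnames(X), names(stats$mean)))
      stop_gaitprog("gaitprog_format_error",
                    "matrix columns do not match scaling stats")
  }
  keep <- colnames(X) %in% stats$columns
  Z <- sweep(X[, keep, drop = FALSE], 2L, stats$mean[keep], "-")
  Z <- sweep(Z, 2L, stats$sd[keep], "/")
  list(matrix = Z, stats = stats)
}
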