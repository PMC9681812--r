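# Progression outcomes: annualized change from baseline in six clinical
# metrics, including the signed-z-score global composite outcome (GCO).

OUTCOME_NAMES <- c("updrs_total", "ledd", "pdq39_mobility", "moca", "se", "gco")
# instruments administered annually are only observed at months 0/12/24,
# so their progression is defined at the 12- and 24-month horizons only
ANNUAL_ONLY_OUTCOMES <- c("pdq39_mobility", "moca", "se", "gco")
GCO_COMPONENTS <- c("updrs1", "updrs2", "updrs3", "se", "moca")
GCO_SIGNS <- c(updrs1 = 1, updrs2 = 1, updrs3 = 1, se = -1, moca = -1)

#' Levodopa-equivalent daily dose
#'
#' Converts per-drug daily doses (mg/day) into a single levodopa-equivalent
#' daily dose by summing dose x factor over all drugs. The default
#' conversion table ([ledd_conversion_factors()]) includes extended-release
#' carbidopa/levodopa (Rytary) at 0.7 and carbidopa/levodopa enteral
#' suspension (Duopa) at 0.97.
#'
#' @param doses Named numeric vector of daily doses in mg/day; names must
#'   appear in `factors`.
#' @param factors Named numeric vector of positive conversion factors.
#' @return LEDD in mg/day.
#' @examples
#' compute_ledd(c(rytary = 435))            # 304.5
#' compute_ledd(c(duopa = 1000))            # 970
#' compute_ledd(c(levodopa = 300, rasagiline = 1))
#' @export
compute_ledd <- function(doses, factors = ledd_conversion_factors()) {
  if (!length(doses)) return(0)
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop_gaitprog("gaitprog_domain_error", "doses must be a named vector")
  if (any(!is.finite(doses)) || any(doses < 0))
    stop_gaitprog("gaitprog_domain_error", "doses must be finite and >= 0")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop_gaitprog("gaitprog_domain_error", "conversion factors must be > 0")
  unknown <- setdiff(names(doses), names(factors))
  if (length(unknown))
    stop_gaitprog("gaitprog_domain_error",
                  "no conversion factor for: %s", paste(unknown, collapse = ", "))
  sum(doses * factors[names(doses)])
}

#' Annual rate of change from baseline
#'
#' Progression for every outcome is the annual rate of change from
#' baseline: (horizon value - baseline value) / elapsed years. Missing
#' values propagate to `NA` (the outcome is undefined, not zero).
#'
#' @param baseline_value,horizon_value Outcome values at baseline and at
#'   the follow-up horizon (vectorized).
#' @param elapsed_years Positive time between the two measurements, years.
#' @return Rate in outcome units per year.
#' @examples
#' annualized_change(36, 38, 0.5)   # 4 points/year
#' annualized_change(600, 839, 2)   # 119.5 mg/day/year
#' @export
annualized_change <- function(baseline_value, horizon_value, elapsed_years) {
  if (any(!is.finite(elapsed_years)) || any(elapsed_years <= 0))
    stop_gaitprog("gaitprog_domain_error", "elapsed_years must be > 0")
  (horizon_value - baseline_value) / elapsed_years
}

#' Reference distribution for the global composite outcome
#'
#' The GCO z-scores five components (MDS-UPDRS parts I, II, III, Schwab &
#' England, MoCA) against a reference population. The reference here is the
#' baseline distribution of a chosen subject group: per-component mean and
#' SD (n-1 denominator) of the subjects' baseline values. The same
#' reference is then applied unchanged to follow-up visits, so change in
#' GCO reflects change in the raw scores.
#'
#' @param cohort A [pd_cohort()].
#' @param subject_ids Subjects whose baseline values define the reference
#'   (default: all subjects with a gait/balance baseline). At least two
#'   must have all five components at baseline.
#' @return A `gco_reference`: data frame with columns `component`, `mean`,
#'   `sd`, `sign` (+1 for UPDRS parts, -1 for S&E and MoCA).
#' @export
fit_gco_reference <- function(cohort, subject_ids = NULL) {
  base <- baseline_clinical(cohort)
  if (!is.null(subject_ids)) base <- base[base$subject_id %in% subject_ids, ]
  comp <- base[GCO_COMPONENTS]
  complete <- stats::complete.cases(comp)
  if (sum(complete) < 2L)
    stop_gaitprog("gaitprog_domain_error",
                  "GCO reference needs >= 2 subjects with all five components at baseline (got %d)",
                  sum(complete))
  comp <- comp[complete, ]
  ref <- data.frame(
    component = GCO_COMPONENTS,
    mean = vapply(comp, mean, numeric(1)),
    sd = vapply(comp, stats::sd, numeric(1)),
    sign = unname(GCO_SIGNS[GCO_COMPONENTS]),
    row.names = NULL
  )
  if (any(ref$sd <= 0))
    stop_gaitprog("gaitprog_degenerate_reference_error",
                  "zero SD in GCO component(s): %s",
                  paste(ref$component[ref$sd <= 0], collapse = ", "))
  class(ref) <- c("gco_reference", "data.frame")
  ref
}

#' Global composite outcome from clinical scores
#'
#' The GCO is the equally weighted average of the signed z-scores of
#' MDS-UPDRS parts I-III, Schwab & England and MoCA. Because higher UPDRS
#' means worse symptoms while higher S&E and MoCA mean better function,
#' the S&E and MoCA z-scores enter with inverted sign, so higher GCO is
#' always worse. Undefined (`NA`) if any component is missing.
#'
#' @param scores A data frame (or single-row list) with columns/elements
#'   `updrs1`, `updrs2`, `updrs3`, `se`, `moca`; vectorized over rows.
#' @param ref A [fit_gco_reference()] object.
#' @return Numeric vector of GCO values in z-units (higher = worse).
#' @export
compute_gco <- function(scores, ref) {
  stopifnot(inherits(ref, "gco_reference"))
  if (!is.data.frame(scores)) scores <- as.data.frame(as.list(scores))
  missing <- setdiff(GCO_COMPONENTS, names(scores))
  if (length(missing))
    stop_gaitprog("gaitprog_format_error",
                  "scores lack GCO component(s): %s", paste(missing, collapse = ", "))
  z <- 0
  for (i in seq_len(nrow(ref))) {
    comp <- ref$component[i]
    z <- z + ref$sign[i] * (scores[[comp]] - ref$mean[i]) / ref$sd[i]
  }
  z / nrow(ref)
}

# clinical rows at each subject's gait/balance baseline visit
baseline_clinical <- function(cohort) {
  bm <- baseline_months(cohort)
  cl <- cohort$clinical
  idx <- match(paste(names(bm), bm), paste(cl$subject_id, cl$nominal_month))
  out <- cl[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify subjects into follow-up groups
#'
#' A subject belongs to the h-month follow-up group when they have
#' baseline gait/balance and clinical data and a clinical visit h months
#' after baseline (baseline being the first visit with gait or balance
#' data). Groups are defined independently, so a subject may belong to
#' several, and group sizes need not be monotone in the horizon.
#'
#' @param cohort A [pd_cohort()].
#' @param horizons Integer months (default 6, 12, 18, 24).
#' @return Named list (one element per horizon, names `"6"`, `"12"`, ...)
#'   of member subject-id character vectors.
#' @export
assign_followup_groups <- function(cohort, horizons = c(6L, 12L, 18L, 24L)) {
  bm <- baseline_months(cohort)
  cl_key <- paste(cohort$clinical$subject_id, cohort$clinical$nominal_month)
  has_visit <- function(ids, months) paste(ids, months) %in% cl_key
  ids <- names(bm)
  has_baseline_clinical <- has_visit(ids, bm)
  out <- lapply(horizons, function(h) {
    ids[has_baseline_clinical & has_visit(ids, bm + h)]
  })
  names(out) <- as.character(horizons)
  out
}

outcome_value <- function(clinical_rows, outcome_name, gco_ref = NULL) {
  if (outcome_name == "gco") {
    compute_gco(clinical_rows, gco_ref)
  } else {
    clinical_rows[[outcome_name]]
  }
}

#' Annualized progression outcomes for every subject and horizon
#'
#' Computes, for each follow-up group and each outcome, the annual rate of
#' change from the baseline visit to the visit at baseline + horizon.
#' MoCA, PDQ-39 mobility, S&E and the GCO are only administered annually,
#' so those outcomes exist at the 12- and 24-month horizons only;
#' MDS-UPDRS total and LEDD are available at all four horizons. The GCO
#' reference population is, by default, the baseline values of the horizon
#' group under analysis ("horizon-group"); `"pooled"` uses all subjects
#' with a baseline instead.
#'
#' @param cohort A [pd_cohort()].
#' @param horizons Follow-up horizons in months.
#' @param outcomes Outcome names among `updrs_total`, `ledd`,
#'   `pdq39_mobility`, `moca`, `se`, `gco`.
#' @param use_elapsed If `TRUE`, annualize by the recorded `elapsed_years`
#'   difference between the two visits; default uses the nominal horizon
#'   (0.5, 1, 1.5 or 2 years).
#' @param gco_reference `"horizon-group"` (default) or `"pooled"`.
#' @return Data frame with columns `subject_id`, `outcome_name`,
#'   `horizon_months`, `annual_rate`; rows only where both baseline and
#'   horizon values exist.
#' @export
compute_outcomes <- function(cohort, horizons = c(6L, 12L, 18L, 24L),
                             outcomes = OUTCOME_NAMES,
                             use_elapsed = FALSE,
                             gco_reference = c("horizon-group", "pooled")) {
  outcomes <- match.arg(outcomes, OUTCOME_NAMES, several.ok = TRUE)
  gco_reference <- match.arg(gco_reference)
  groups <- assign_followup_groups(cohort, horizons)
  bm <- baseline_months(cohort)
  cl <- cohort$clinical
  cl_key <- paste(cl$subject_id, cl$nominal_month)
  pooled_ref <- NULL
  if ("gco" %in% outcomes && gco_reference == "pooled")
    pooled_ref <- fit_gco_reference(cohort)

  pieces <- list()
  for (h in horizons) {
    members <- groups[[as.character(h)]]
    if (!length(members)) next
    b_idx <- match(paste(members, bm[members]), cl_key)
    h_idx <- match(paste(members, bm[members] + h), cl_key)
    b_rows <- cl[b_idx, , drop = FALSE]
    h_rows <- cl[h_idx, , drop = FALSE]
    years <- if (use_elapsed) {
      ey <- function(rows) ifelse(is.na(rows$elapsed_years),
                                  rows$nominal_month / 12, rows$elapsed_years)
      ey(h_rows) - ey(b_rows)
    } else rep(h / 12, length(members))

    for (oc in outcomes) {
      if (oc %in% ANNUAL_ONLY_OUTCOMES && !h %in% c(12L, 24L)) next
      ref <- NULL
      if (oc == "gco")
        ref <- if (gco_reference == "pooled") pooled_ref
               else fit_gco_reference(cohort, members)
      vb <- outcome_value(b_rows, oc, ref)
      vh <- outcome_value(h_rows, oc, ref)
      ok <- !is.na(vb) & !is.na(vh) & years > 0
      if (!any(ok)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        subject_id = members[ok],
        outcome_name = oc,
        horizon_months = as.integer(h),
        annual_rate = annualized_change(vb[ok], vh[ok], years[ok])
      )
    }
  }
  if (!length(pieces))
    return(data.frame(subject_id = character(0), outcome_name = character(0),
                      horizon_months = integer(0), annual_rate = numeric(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Median and quartiles of annualized change
#'
#' Summarizes one outcome x horizon cell of the progression table: sample
#' median and first/third quartiles (linear interpolation between order
#' statistics) of the annual rates, in outcome units per year.
#'
#' @param outcomes Data frame from [compute_outcomes()].
#' @param outcome_name,horizon_months Cell selectors.
#' @return Named numeric vector `c(n, median, q1, q3)`.
#' @export
summarize_median_change <- function(outcomes, outcome_name, horizon_months) {
  rates <- outcomes$annual_rate[outcomes$outcome_name == outcome_name &
                                  outcomes$horizon_months == horizon_months]
  if (!length(rates))
    stop_gaitprog("gaitprog_domain_error",
                  "no defined outcomes for %s at %d months",
                  outcome_name, horizon_months)
  q <- stats::quantile(rates, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(n = length(rates), median = q[2], q1 = q[1], q3 = q[3])
}

#' Median-change report across all outcomes and horizons
#'
#' Builds the median (Q1, Q3) annual-change table: one row per outcome,
#' one column group per horizon; cells where an outcome is undefined at a
#' horizon (annual-only instruments at 6 and 18 months) are `NA`.
#'
#' @param outcomes Data frame from [compute_outcomes()].
#' @param horizons Horizons to tabulate.
#' @return Data frame with columns `outcome_name`, `horizon_months`, `n`,
#'   `median`, `q1`, `q3` (long layout).
#' @export
median_change_table <- function(outcomes, horizons = c(6L, 12L, 18L, 24L)) {
  grid <- expand.grid(outcome_name = OUTCOME_NAMES, horizon_months = horizons,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    oc <- grid$outcome_name[i]; h <- grid$horizon_months[i]
    cell <- data.frame(outcome_name = oc, horizon_months = as.integer(h),
                       n = NA_integer_, median = NA_real_,
                       q1 = NA_real_, q3 = NA_real_)
    has <- any(outcomes$outcome_name == oc & outcomes$horizon_months == h)
    if (has) {
      s <- summarize_median_change(outcomes, oc, h)
      cell$n <- as.integer(s[["n"]]); cell$median <- s[["median"]]
      cell$q1 <- s[["q1"]]; cell$q3 <- s[["q3"]]
    }
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
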