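# Longitudinal cohort container: three tidy data frames.
#   subjects : one row per subject (demographics)
#   clinical : one row per visit (clinical instruments)
#   features : one row per trial x parameter (gait/balance panels, long)

VISIT_MONTHS <- c(0L, 6L, 12L, 18L, 24L)
ANNUAL_MONTHS <- c(0L, 12L, 24L)   # MoCA / PDQ-39 / S&E administered annually

SUBJECT_COLS <- c("subject_id", "sex", "ethnicity", "age",
                  "education_years", "disease_duration_years")
CLINICAL_COLS <- c("subject_id", "nominal_month", "elapsed_years",
                   "updrs1", "updrs2", "updrs3", "updrs4", "updrs_total",
                   "hy", "ledd", "se", "moca", "pdq39_mobility",
                   "hama", "hamd", "epworth", "upsit")
FEATURE_COLS <- c("subject_id", "nominal_month", "panel", "trial_index",
                  "parameter", "value")

stop_gaitprog <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "gaitprog_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Assemble and validate a longitudinal cohort
#'
#' Bundles the three tidy tables of the data model -- subject demographics,
#' per-visit clinical instruments, and per-trial gait/balance feature values
#' in long format -- into a validated `pd_cohort` object. Validation
#' enforces the structural invariants of the data model: unique subject
#' ids, visits resolving to known subjects, at most one visit per subject
#' per nominal month, trial indices 1-3, and feature parameter names drawn
#' from the canonical per-panel name sets (46 for iSway1, 33 for iSway2,
#' 96 for iTUG).
#'
#' @param subjects Data frame with columns `subject_id`, `sex`,
#'   `ethnicity`, `age`, `education_years`, `disease_duration_years`.
#' @param clinical Data frame with columns `subject_id`, `nominal_month`,
#'   `elapsed_years` (NA means the nominal month / 12), the MDS-UPDRS parts
#'   `updrs1`..`updrs4` and `updrs_total`, `hy`, `ledd`, `se`, `moca`,
#'   `pdq39_mobility`, and the descriptive-only fields `hama`, `hamd`,
#'   `epworth`, `upsit`. Missing values are `NA`, never sentinels.
#' @param features Long data frame with columns `subject_id`,
#'   `nominal_month`, `panel`, `trial_index`, `parameter`, `value`.
#' @return An object of class `pd_cohort`: a list of the three validated
#'   data frames.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
pd_cohort <- function(subjects, clinical, features) {
  subjects <- check_columns(subjects, SUBJECT_COLS, "demographics")
  clinical <- check_columns(clinical, CLINICAL_COLS, "clinical")
  features <- check_columns(features, FEATURE_COLS, "features")

  subjects$subject_id <- as.character(subjects$subject_id)
  clinical$subject_id <- as.character(clinical$subject_id)
  features$subject_id <- as.character(features$subject_id)

  if (anyDuplicated(subjects$subject_id))
    stop_gaitprog("gaitprog_integrity_error",
                  "duplicate subject_id in demographics: %s",
                  paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
                        collapse = ", "))
  bad_age <- which(!is.na(subjects$age) & subjects$age <= 0)
  if (length(bad_age))
    stop_gaitprog("gaitprog_format_error",
                  "age_at_baseline must be > 0 (rows %s of demographics)",
                  paste(bad_age, collapse = ", "))
  bad_dd <- which(!is.na(subjects$disease_duration_years) &
                    subjects$disease_duration_years < 0)
  if (length(bad_dd))
    stop_gaitprog("gaitprog_format_error",
                  "disease_duration_years must be >= 0 (rows %s)",
                  paste(bad_dd, collapse = ", "))

  for (tab in list(clinical = clinical, features = features)) {
    unknown <- setdiff(unique(tab$subject_id), subjects$subject_id)
    if (length(unknown))
      stop_gaitprog("gaitprog_integrity_error",
                    "visit rows reference unknown subject(s): %s",
                    paste(unknown, collapse = ", "))
  }

  bad_month <- which(!clinical$nominal_month %in% VISIT_MONTHS)
  if (length(bad_month))
    stop_gaitprog("gaitprog_format_error",
                  "nominal_month must be one of {%s} (clinical rows %s)",
                  paste(VISIT_MONTHS, collapse = ", "),
                  paste(bad_month, collapse = ", "))
  key <- paste(clinical$subject_id, clinical$nominal_month)
  if (anyDuplicated(key))
    stop_gaitprog("gaitprog_integrity_error",
                  "duplicate (subject, month) visit: %s",
                  paste(unique(key[duplicated(key)]), collapse = "; "))
  bad_ey <- which(!is.na(clinical$elapsed_years) & clinical$nominal_month > 0 &
                    clinical$elapsed_years <= 0)
  if (length(bad_ey))
    stop_gaitprog("gaitprog_format_error",
                  "elapsed_years must be > 0 for post-baseline visits (rows %s)",
                  paste(bad_ey, collapse = ", "))
  check_clinical_ranges(clinical)

  bad_panel <- which(!features$panel %in% panel_names())
  if (length(bad_panel))
    stop_gaitprog("gaitprog_schema_error",
                  "unknown panel name(s): %s",
                  paste(unique(features$panel[bad_panel]), collapse = ", "))
  bad_trial <- which(!features$trial_index %in% 1:3)
  if (length(bad_trial))
    stop_gaitprog("gaitprog_format_error",
                  "trial_index must be 1, 2 or 3 (feature rows %s)",
                  paste(utils::head(bad_trial, 5L), collapse = ", "))
  for (p in unique(features$panel)) {
    canon <- panel_parameters(p)
    seen <- unique(features$parameter[features$panel == p])
    rogue <- setdiff(seen, canon)
    if (length(rogue))
      stop_gaitprog("gaitprog_schema_error",
                    "parameter(s) not in the %s panel: %s",
                    p, paste(utils::head(rogue, 5L), collapse = ", "))
  }
  fkey <- paste(features$subject_id, features$nominal_month, features$panel,
                features$trial_index, features$parameter)
  if (anyDuplicated(fkey))
    stop_gaitprog("gaitprog_integrity_error",
                  "duplicate feature rows (same subject/month/panel/trial/parameter)")

  structure(list(subjects = subjects, clinical = clinical,
                 features = features),
            class = "pd_cohort")
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df))
    stop_gaitprog("gaitprog_format_error", "%s table must be a data frame", what)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_gaitprog("gaitprog_format_error",
                  "%s table is missing required column(s): %s",
                  what, paste(missing, collapse = ", "))
  df <- df[cols]
  rownames(df) <- NULL
  df
}

check_clinical_ranges <- function(cl) {
  chk <- function(col, ok, what) {
    x <- cl[[col]]
    bad <- which(!is.na(x) & !ok(x))
    if (length(bad))
      stop_gaitprog("gaitprog_format_error", "%s (%s; clinical rows %s)",
                    what, col, paste(utils::head(bad, 5L), collapse = ", "))
  }
  nonneg_int <- function(x) x >= 0 & x == round(x)
  for (p in c("updrs1", "updrs2", "updrs3", "updrs4", "updrs_total"))
    chk(p, nonneg_int, "UPDRS scores must be non-negative integers")
  chk("hy", function(x) x >= 1 & x <= 5 & (2 * x) == round(2 * x),
      "H&Y must be on the 1-5 half-point scale")
  chk("ledd", function(x) x >= 0, "LEDD must be >= 0 mg/day")
  chk("se", function(x) x >= 0 & x <= 1 & abs(x * 10 - round(x * 10)) < 1e-8,
      "S&E must lie on the 0, 0.1, ..., 1 grid")
  chk("moca", function(x) nonneg_int(x) & x <= 31,
      "MoCA must be an integer in 0-31")
  chk("pdq39_mobility", function(x) x >= 0 & x <= 100,
      "PDQ-39 mobility must be a percent in 0-100")
  parts <- cl[c("updrs1", "updrs2", "updrs3", "updrs4")]
  full <- stats::complete.cases(parts) & !is.na(cl$updrs_total)
  mism <- which(full & rowSums(parts) != cl$updrs_total)
  if (length(mism))
    stop_gaitprog("gaitprog_integrity_error",
                  "updrs_total != sum of parts (clinical rows %s)",
                  paste(utils::head(mism, 5L), collapse = ", "))
  invisible(cl)
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort> %d subjects, %d visits, %d feature rows\n",
              nrow(x$subjects), nrow(x$clinical), nrow(x$features)))
  bm <- baseline_months(x)
  cat(sprintf("  subjects with gait/balance baseline: %d\n", length(bm)))
  invisible(x)
}

#' First visit with gait or balance data, per subject
#'
#' The baseline visit for the analysis is defined as the first visit at
#' which any gait or balance data are available for the subject; subjects
#' with no feature data anywhere have no baseline and are excluded.
#'
#' @param cohort A [pd_cohort()] object.
#' @return Named integer vector: for each subject with any feature data,
#'   the nominal month of their baseline visit.
#' @export
baseline_months <- function(cohort) {
  stopifnot(inherits(cohort, "pd_cohort"))
  if (!nrow(cohort$features)) return(stats::setNames(integer(0), character(0)))
  bm <- tapply(cohort$features$nominal_month, cohort$features$subject_id, min)
  bm <- stats::setNames(as.integer(bm), names(bm))
  bm[order(names(bm))]
}

cohort_paths <- function(dir_or_paths) {
  if (is.character(dir_or_paths) && length(dir_or_paths) == 1L &&
      is.null(names(dir_or_paths))) {
    d <- dir_or_paths
    return(c(demographics = file.path(d, "demographics.csv"),
             clinical = file.path(d, "clinical.csv"),
             features = file.path(d, "features.csv")))
  }
  need <- c("demographics", "clinical", "features")
  p <- unlist(dir_or_paths)
  if (!all(need %in% names(p)))
    stop_gaitprog("gaitprog_format_error",
                  "paths must name demographics, clinical and features files")
  p[need]
}

#' Read a cohort from delimited text files
#'
#' Reads the three comma-delimited, UTF-8, headered tables of the cohort
#' data model (`demographics.csv`, `clinical.csv`, `features.csv`) and
#' returns a validated [pd_cohort()]. Empty fields are missing values;
#' rows violating the data-model invariants abort with a classed error
#' identifying the offending rows.
#'
#' @param paths Either a directory containing the three canonical file
#'   names, or a named character vector/list with elements `demographics`,
#'   `clinical`, `features`.
#' @return A validated [pd_cohort()].
#' @export
read_cohort <- function(paths) {
  p <- cohort_paths(paths)
  for (f in p) if (!file.exists(f))
    stop_gaitprog("gaitprog_format_error", "file not found: %s", f)
  read1 <- function(path, classes) {
    utils::read.csv(path, colClasses = classes, na.strings = "",
                    fileEncoding = "UTF-8", check.names = TRUE)
  }
  subjects <- read1(p[["demographics"]],
                    c(subject_id = "character", sex = "character",
                      ethnicity = "character", age = "numeric",
                      education_years = "numeric",
                      disease_duration_years = "numeric"))
  clinical <- read1(p[["clinical"]],
                    c(subject_id = "character", nominal_month = "integer"))
  features <- read1(p[["features"]],
                    c(subject_id = "character", nominal_month = "integer",
                      panel = "character", trial_index = "integer",
                      parameter = "character", value = "numeric"))
  pd_cohort(subjects, clinical, features)
}

#' Write a cohort to delimited text files
#'
#' Writes the three tables of a [pd_cohort()] as comma-delimited UTF-8 CSV
#' with header rows. Missing values become empty fields (never 0 or any
#' sentinel), and numeric values are written with enough digits that
#' [read_cohort()] restores them bit-for-bit: read-after-write is the
#' identity on valid cohorts.
#'
#' @param cohort A [pd_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_gaitprog("gaitprog_io_error",
                           "cannot create output directory: %s", dir)
  }
  p <- cohort_paths(dir)
  write1 <- function(df, path) {
    out <- df
    quote_cols <- which(vapply(df, is.character, logical(1)))
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        # 17 significant digits: doubles survive the round trip exactly
        x <- formatC(out[[j]], digits = 17, format = "g")
        x[is.na(out[[j]])] <- NA
        out[[j]] <- x
      }
    }
    ok <- tryCatch({
      utils::write.csv(out, path, row.names = FALSE, na = "",
                       fileEncoding = "UTF-8", quote = quote_cols)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_gaitprog("gaitprog_io_error", "cannot write %s", path)
  }
  write1(cohort$subjects, p[["demographics"]])
  write1(cohort$clinical, p[["clinical"]])
  write1(cohort$features, p[["features"]])
  invisible(p)
}

#' Subjects eligible for the analysis
#'
#' A subject is analyzable when they have at least two clinical
#' assessments (baseline and one post-baseline visit) and at least one
#' visit with gait or balance data.
#'
#' @param cohort A [pd_cohort()].
#' @return Character vector of analyzable subject ids.
#' @export
analyzable_subjects <- function(cohort) {
  bm <- baseline_months(cohort)
  if (!length(bm)) return(character(0))
  ids <- names(bm)
  keep <- vapply(ids, function(id) {
    months <- cohort$clinical$nominal_month[cohort$clinical$subject_id == id]
    any(months == bm[[id]]) && any(months > bm[[id]])
  }, logical(1))
  ids[keep]
}
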