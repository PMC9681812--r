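#' Gait and balance panel definitions
#'
#' The pipeline works with three instrumented test panels produced by
#' body-worn inertial sensors: the instrumented Timed-Up-and-Go (iTUG, 96
#' computed parameters), the instrumented postural sway test version 1
#' (iSway1, 46 parameters) and its version-2 recalculation (iSway2, 33
#' parameters). The native parameter names are proprietary to the motion
#' analysis software, so the package ships stable synthetic identifiers
#' (`itug_p001` ... `itug_p096`, and likewise for the sway panels); only the
#' counts and the stability of the name sets matter to the analysis.
#'
#' @param panel One of `"iSway1"`, `"iSway2"`, `"iTUG"`.
#' @return `panel_parameters()`: character vector of canonical parameter
#'   names for the panel. `panel_names()`: the three panel labels.
#'   `panel_configs()`: the five single/combined panel configurations used
#'   in modelling.
#' @examples
#' length(panel_parameters("iTUG"))   # 96
#' panel_configs()
#' @export
panel_parameters <- function(panel) {
  panel <- match.arg(panel, panel_names())
  n <- c(iSway1 = 46L, iSway2 = 33L, iTUG = 96L)[[panel]]
  prefix <- c(iSway1 = "isway1", iSway2 = "isway2", iTUG = "itug")[[panel]]
  sprintf("%s_p%03d", prefix, seq_len(n))
}

#' @rdname panel_parameters
#' @export
panel_names <- function() c("iSway1", "iSway2", "iTUG")

#' @rdname panel_parameters
#' @export
panel_configs <- function() {
  c("iSway1", "iSway2", "iTUG", "iSway1+iTUG", "iSway2+iTUG")
}

# panels making up a configuration, e.g. "iSway1+iTUG" -> c("iSway1","iTUG")
config_panels <- function(panel_config) {
  panel_config <- match.arg(panel_config, panel_configs())
  strsplit(panel_config, "+", fixed = TRUE)[[1L]]
}

#' Levodopa-equivalent dose conversion factors
#'
#' Per-drug multipliers mapping daily dose (mg/day) to levodopa-equivalent
#' mg/day. The table follows the standard conversion convention, modified to
#' incorporate extended-release carbidopa/levodopa capsules (Rytary) at a
#' factor of 0.7 and carbidopa/levodopa enteral suspension (Duopa) at 0.97.
#' Users may supply their own named factor vector anywhere a conversion
#' table is accepted; only drugs present in the table can contribute.
#'
#' @return Named numeric vector of conversion factors.
#' @examples
#' ledd_conversion_factors()[["rytary"]]  # 0.7
#' @export
ledd_conversion_factors <- function() {
  c(
    levodopa            = 1,
    levodopa_cr         = 0.75,
    rytary              = 0.7,
    duopa               = 0.97,
    entacapone_ld       = 0.33,  # applied to the concomitant levodopa dose
    pramipexole         = 100,
    ropinirole          = 20,
    rotigotine          = 30,
    selegiline_oral     = 10,
    rasagiline          = 100,
    amantadine          = 1
  )
}
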