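#' Replicate-noise calibration for a target mean ratio
#'
#' For two band densities with independent multiplicative `N(0, cv^2)`
#' errors around a true ratio of 1, the expected min/max ratio expands to
#' `1 - (2/sqrt(pi)) cv + cv^2 + O(cv^3)`. Given a target replicate mean
#' `m`, the calibrated cv is the smaller root of
#' `cv^2 - (2/sqrt(pi)) cv + (1 - m) = 0`. This closed form is how the
#' reproducibility presets encode their published row means; no numerical
#' tuning is involved.
#'
#' @param target_mean expected replicate mean ratio, in (0.6, 1].
#' @return the calibrated coefficient of variation.
#' @export
replicate_cv_for_mean <- function(target_mean) {
  check_scalar(target_mean, "target_mean", lo = 0.6, hi = 1, open_lo = TRUE)
  b <- 2 / sqrt(pi)
  deficit <- 1 - target_mean
  disc <- b^2 - 4 * deficit
  if (disc < 0)
    stop("target_mean too far below 1 for the small-cv model",
         call. = FALSE)
  (b - sqrt(disc)) / 2
}

# Table of reproducibility rows the replicate presets encode:
# a cell line (SW480) and four white-blood-cell normal controls.
table2_means <- c("table2-sw480" = 0.989,
                  "table2-wbc1" = 0.980,
                  "table2-wbc2" = 0.967,
                  "table2-wbc3" = 0.954,
                  "table2-wbc4" = 0.921)

#' Named simulation presets
#'
#' Registry of ready-made configuration bundles:
#' \describe{
#'   \item{`"figure1b"`}{dilution-series calibration: an SW480-like cell
#'     line over the 2-fold load grid 1.25-40 ug, with the amplitude scale
#'     chosen so the smallest load at which both bands pass the default
#'     detectability rule is 10 ug.}
#'   \item{`"figure3"`}{screening cohort: N = 50 at-risk subjects, 25%
#'     carrier prevalence split evenly between MLH1 and MSH2, ratio
#'     components 0.97 +/- 0.02 (non-carrier) and 0.81 +/- 0.08 (carrier),
#'     floored at 0.3.}
#'   \item{`"table2-sw480"`, `"table2-wbc1"` ... `"table2-wbc4"`}{replicate
#'     noise levels reproducing the published reproducibility panel row
#'     means (0.989, 0.980, 0.967, 0.954, 0.921); `"table2-wbc"` is an
#'     alias for `"table2-wbc1"`, the default white-blood-cell control
#'     noise level.}
#' }
#'
#' @param name preset name.
#' @return a list bundle; fields depend on the preset `kind`
#'   (`"dilution"`, `"cohort"`, or `"replicate"`).
#' @export
mmr_preset <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "table2-wbc") name <- "table2-wbc1"
  if (name %in% names(table2_means)) {
    target <- table2_means[[name]]
    is_wbc <- grepl("wbc", name)
    return(list(kind = "replicate", name = name,
                target_mean = target,
                cv = replicate_cv_for_mean(target),
                subject = if (is_wbc)
                  subject_spec("WBC", cell_type = "fresh_lymphocyte")
                else subject_spec("SW480", cell_type = "cell_line"),
                blot = blot_config(),
                stim = stimulation_params()))
  }
  switch(name,
         figure1b = list(kind = "dilution", name = name,
                         blot = blot_config(amplitude_per_unit = 4,
                                            noise_sd = 3, seed = 101L),
                         loads_ug = c(1.25, 2.5, 5, 10, 20, 40),
                         subject = subject_spec("SW480",
                                                cell_type = "cell_line"),
                         stim = stimulation_params(),
                         lod_abs = 300, lod_snr = 3),
         figure3 = list(kind = "cohort", name = name,
                        cohort = cohort_config(),
                        blot = blot_config(),
                        stim = stimulation_params(),
                        lod_abs = 300, lod_snr = 3),
         stop(sprintf("unknown preset '%s'; available: %s", name,
                      paste(mmr_presets(), collapse = ", ")),
              call. = FALSE))
}

#' @rdname mmr_preset
#' @export
mmr_presets <- function() {
  c("figure1b", "figure3", names(table2_means), "table2-wbc")
}
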