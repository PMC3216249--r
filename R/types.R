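#' Subject specification for lane simulation
#'
#' Describes one biological sample: the cell type (which controls the PHA
#' stimulation response), the germline carrier status, per-protein baseline
#' expression in arbitrary units, and the gene-dosage factor applied to the
#' mutated protein in carriers. A heterozygous truncating mutation is
#' expected to reduce full-length protein output from that locus, which is
#' what `dosage_factor` encodes.
#'
#' Base abundances may be zero to represent a null control line (e.g. a cell
#' line expressing only one of the two proteins); they may not be negative.
#' `dosage_factor` must be 1 for non-carriers.
#'
#' @param subject_id character identifier.
#' @param cell_type one of `"fresh_lymphocyte"`, `"immortalized_lymphocyte"`,
#'   `"monocyte"`, `"cell_line"`.
#' @param carrier_status one of `"non_carrier"`, `"mlh1_carrier"`,
#'   `"msh2_carrier"`.
#' @param base_abundance_mlh1,base_abundance_msh2 non-negative baseline
#'   expression (arbitrary units).
#' @param dosage_factor multiplier in (0, 1] applied to the mutated protein's
#'   abundance for carriers; must be 1 for non-carriers.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id,
                         cell_type = c("fresh_lymphocyte",
                                       "immortalized_lymphocyte",
                                       "monocyte", "cell_line"),
                         carrier_status = c("non_carrier", "mlh1_carrier",
                                            "msh2_carrier"),
                         base_abundance_mlh1 = 1,
                         base_abundance_msh2 = 1,
                         dosage_factor = 1) {
  cell_type <- match.arg(cell_type)
  carrier_status <- match.arg(carrier_status)
  check_scalar(base_abundance_mlh1, "base_abundance_mlh1", lo = 0)
  check_scalar(base_abundance_msh2, "base_abundance_msh2", lo = 0)
  check_scalar(dosage_factor, "dosage_factor", lo = 0, hi = 1, open_lo = TRUE)
  if (carrier_status == "non_carrier" && dosage_factor != 1)
    stop("dosage_factor must be 1 for non-carriers", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 cell_type = cell_type,
                 carrier_status = carrier_status,
                 base_abundance_mlh1 = base_abundance_mlh1,
                 base_abundance_msh2 = base_abundance_msh2,
                 dosage_factor = dosage_factor),
            class = "subject_spec")
}

#' Effective per-protein abundances after the carrier dosage effect
#'
#' @param subject a [subject_spec()].
#' @return named numeric vector `c(MLH1 = ..., MSH2 = ...)`.
#' @export
effective_abundances <- function(subject) {
  stopifnot(inherits(subject, "subject_spec"))
  a <- c(MLH1 = subject$base_abundance_mlh1,
         MSH2 = subject$base_abundance_msh2)
  if (subject$carrier_status == "mlh1_carrier")
    a["MLH1"] <- a["MLH1"] * subject$dosage_factor
  if (subject$carrier_status == "msh2_carrier")
    a["MSH2"] <- a["MSH2"] * subject$dosage_factor
  a
}

#' PHA stimulation parameters
#'
#' Fresh lymphocytes express little MMR protein at rest; the mitogen PHA
#' drives them into proliferation and raises MLH1/MSH2 expression in a dose-
#' and time-dependent, saturating way. The model is a hyperbolic dose term
#' times an exponential rise in time (see [stimulation_multiplier()]).
#'
#' Defaults place the half-saturation dose at 5 ug and the rise time constant
#' at 24 h, so the routine stimulation protocol (10 ug PHA, 48 h) reaches
#' ~60% of maximal expression, while unstimulated fresh-lymphocyte bands sit
#' below the default detection limit.
#'
#' @param pha_dose PHA dose in ug (non-negative).
#' @param time_hr stimulation time in hours (non-negative).
#' @param K_d half-saturation dose in ug (positive).
#' @param tau rise time constant in hours (positive).
#' @param E0_frac unstimulated fraction of maximal expression, in `[0, 1)`.
#' @return an object of class `stimulation_params`.
#' @export
stimulation_params <- function(pha_dose = 10, time_hr = 48,
                               K_d = 5, tau = 24, E0_frac = 0.05) {
  check_scalar(pha_dose, "pha_dose", lo = 0)
  check_scalar(time_hr, "time_hr", lo = 0)
  check_scalar(K_d, "K_d", lo = 0, open_lo = TRUE)
  check_scalar(tau, "tau", lo = 0, open_lo = TRUE)
  check_scalar(E0_frac, "E0_frac", lo = 0, hi = 1, open_hi = TRUE)
  structure(list(pha_dose = pha_dose, time_hr = time_hr, K_d = K_d,
                 tau = tau, E0_frac = E0_frac),
            class = "stimulation_params")
}

#' Blot geometry and film model configuration
#'
#' Lanes run along a migration axis of `migration_axis_length` pixels.
#' MSH2 (100 kDa) migrates less far than MLH1 (80 kDa), so its band center
#' sits above (at a smaller pixel index than) the MLH1 band. Bands are
#' Gaussian with common width `band_sigma`; the film background is a linear
#' ramp plus additive Gaussian pixel noise. Band peak amplitude is
#' `amplitude_per_unit * protein_load_ug * abundance * stimulation`.
#'
#' The two band windows (center +/- 3 sigma) must not overlap.
#'
#' @param migration_axis_length profile length in pixels.
#' @param lane_width lane width in pixels (image simulation).
#' @param band_center_msh2,band_center_mlh1 band centers in pixels (1-based).
#' @param band_sigma Gaussian band SD in pixels.
#' @param background_level film background at the top of the lane.
#' @param background_slope background drift per pixel along the axis.
#' @param noise_sd SD of additive Gaussian noise at profile level.
#' @param amplitude_per_unit density units per (expression unit x ug load).
#' @param protein_load_ug total protein loaded per lane, ug.
#' @param seed integer seed for the lane/image noise.
#' @return an object of class `blot_config`.
#' @export
blot_config <- function(migration_axis_length = 120L,
                        lane_width = 10L,
                        band_center_msh2 = 40,
                        band_center_mlh1 = 80,
                        band_sigma = 4,
                        background_level = 100,
                        background_slope = 0.1,
                        noise_sd = 3,
                        amplitude_per_unit = 50,
                        protein_load_ug = 10,
                        seed = 1L) {
  check_scalar(migration_axis_length, "migration_axis_length", lo = 1)
  check_scalar(lane_width, "lane_width", lo = 1)
  check_scalar(band_sigma, "band_sigma", lo = 0, open_lo = TRUE)
  check_scalar(background_level, "background_level", lo = 0)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  check_scalar(amplitude_per_unit, "amplitude_per_unit", lo = 0,
               open_lo = TRUE)
  check_scalar(protein_load_ug, "protein_load_ug", lo = 0, open_lo = TRUE)
  L <- as.integer(migration_axis_length)
  for (ctr in c(band_center_msh2, band_center_mlh1))
    check_scalar(ctr, "band center", lo = 1, hi = L)
  w <- band_windows_nominal(band_center_msh2, band_center_mlh1, band_sigma, L)
  if (w$MSH2[2] >= w$MLH1[1] && w$MSH2[1] <= w$MLH1[2])
    stop("band windows (center +/- 3*sigma) overlap; ",
         "increase center separation or decrease band_sigma", call. = FALSE)
  structure(list(migration_axis_length = L,
                 lane_width = as.integer(lane_width),
                 band_center_msh2 = band_center_msh2,
                 band_center_mlh1 = band_center_mlh1,
                 band_sigma = band_sigma,
                 background_level = background_level,
                 background_slope = background_slope,
                 noise_sd = noise_sd,
                 amplitude_per_unit = amplitude_per_unit,
                 protein_load_ug = protein_load_ug,
                 seed = as.integer(seed)),
            class = "blot_config")
}

# internal: nominal integration windows, 1-based inclusive pixel intervals
band_windows_nominal <- function(center_msh2, center_mlh1, sigma, L) {
  half <- ceiling(3 * sigma)
  clip <- function(ctr) c(max(1L, as.integer(round(ctr)) - half),
                          min(L, as.integer(round(ctr)) + half))
  list(MSH2 = clip(center_msh2), MLH1 = clip(center_mlh1))
}

#' Cohort generator configuration
#'
#' Subjects are drawn carrier/non-carrier with probability
#' `carrier_prevalence`; carriers split between MLH1 and MSH2 mutations by
#' `gene_split`. Each subject's true MMR ratio target is drawn from the
#' corresponding normal component truncated to `[ratio_floor, 1]` and then
#' converted to protein abundances (affected = unaffected x ratio).
#'
#' Defaults encode a screening cohort of 50 at-risk subjects with 25%
#' carrier prevalence and ratio components 0.97 +/- 0.02 (non-carrier) and
#' 0.81 +/- 0.08 (carrier), floored at 0.3.
#'
#' @param n_subjects number of subjects.
#' @param carrier_prevalence probability a subject is a carrier, in `[0,1]`.
#' @param gene_split fraction of carriers that are MLH1 carriers, in `[0,1]`.
#' @param noncarrier_ratio_mean,noncarrier_ratio_sd non-carrier ratio
#'   component.
#' @param carrier_ratio_mean,carrier_ratio_sd carrier ratio component; the
#'   carrier mean must lie below the non-carrier mean.
#' @param ratio_floor lower truncation bound for generated ratios, in (0,1].
#' @param seed integer master seed; subject `i` uses the deterministic child
#'   stream `child_seed(seed, paste0("subject-", i))`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50L,
                          carrier_prevalence = 0.25,
                          gene_split = 0.5,
                          noncarrier_ratio_mean = 0.97,
                          noncarrier_ratio_sd = 0.02,
                          carrier_ratio_mean = 0.81,
                          carrier_ratio_sd = 0.08,
                          ratio_floor = 0.3,
                          seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lo = 1)
  check_scalar(carrier_prevalence, "carrier_prevalence", lo = 0, hi = 1)
  check_scalar(gene_split, "gene_split", lo = 0, hi = 1)
  check_scalar(noncarrier_ratio_sd, "noncarrier_ratio_sd", lo = 0)
  check_scalar(carrier_ratio_sd, "carrier_ratio_sd", lo = 0)
  check_scalar(ratio_floor, "ratio_floor", lo = 0, hi = 1, open_lo = TRUE)
  if (!(carrier_ratio_mean < noncarrier_ratio_mean))
    stop("carrier_ratio_mean must be below noncarrier_ratio_mean",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 carrier_prevalence = carrier_prevalence,
                 gene_split = gene_split,
                 noncarrier_ratio_mean = noncarrier_ratio_mean,
                 noncarrier_ratio_sd = noncarrier_ratio_sd,
                 carrier_ratio_mean = carrier_ratio_mean,
                 carrier_ratio_sd = carrier_ratio_sd,
                 ratio_floor = ratio_floor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Lane intensity profile
#'
#' A 1-D trace of integrated intensity along the migration axis for one lane,
#' either simulated directly or obtained by summing image columns across the
#' lane width.
#'
#' @param positions strictly increasing integer pixel indices (1-based).
#' @param intensities numeric vector, same length as `positions`.
#' @param lane_id character identifier.
#' @param calibration optional function or data.frame mapping pixel to kDa.
#' @return an object of class `lane_profile`.
#' @export
lane_profile <- function(positions, intensities, lane_id,
                         calibration = NULL) {
  positions <- as.integer(positions)
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length", call. = FALSE)
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  structure(list(positions = positions,
                 intensities = as.numeric(intensities),
                 lane_id = as.character(lane_id),
                 calibration = calibration),
            class = "lane_profile")
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec> %s: %s, %s (MLH1 %.3g, MSH2 %.3g, dosage %.3g)\n",
              x$subject_id, x$cell_type, x$carrier_status,
              x$base_abundance_mlh1, x$base_abundance_msh2, x$dosage_factor))
  invisible(x)
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> %s: %d positions, intensity range [%.4g, %.4g]\n",
              x$lane_id, length(x$positions),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.blot_config <- function(x, ...) {
  cat(sprintf(
    "<blot_config> axis %d px, lane %d px, MSH2@%g MLH1@%g (sigma %g)\n",
    x$migration_axis_length, x$lane_width, x$band_center_msh2,
    x$band_center_mlh1, x$band_sigma))
  cat(sprintf("  background %g + %g/px, noise sd %g, amp/unit %g, load %g ug\n",
              x$background_level, x$background_slope, x$noise_sd,
              x$amplitude_per_unit, x$protein_load_ug))
  invisible(x)
}
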