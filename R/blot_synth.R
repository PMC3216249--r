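#' PHA stimulation multiplier
#'
#' Multiplier in `[E0_frac, 1)` applied to MMR protein expression. Fresh
#' lymphocytes respond to the mitogen with a saturating dose term and an
#' exponential rise in time:
#' \deqn{m = E_0 + (1 - E_0)\,\frac{d}{d + K_d}\,(1 - e^{-t/\tau})}
#' Immortalized lymphocytes and established cell lines are already
#' proliferative: they express maximally (`m = 1`) regardless of PHA.
#' Monocytes do not respond and stay at the unstimulated fraction `E0_frac`.
#'
#' @param params a [stimulation_params()].
#' @param cell_type one of `"fresh_lymphocyte"`, `"immortalized_lymphocyte"`,
#'   `"monocyte"`, `"cell_line"`.
#' @return a single multiplier; non-decreasing in dose and time for fresh
#'   lymphocytes, constant otherwise.
#' @export
stimulation_multiplier <- function(params,
                                   cell_type = c("fresh_lymphocyte",
                                                 "immortalized_lymphocyte",
                                                 "monocyte", "cell_line")) {
  stopifnot(inherits(params, "stimulation_params"))
  cell_type <- match.arg(cell_type)
  switch(cell_type,
         fresh_lymphocyte = {
           d <- params$pha_dose; t <- params$time_hr
           params$E0_frac + (1 - params$E0_frac) *
             (d / (d + params$K_d)) * (1 - exp(-t / params$tau))
         },
         immortalized_lymphocyte = 1,
         cell_line = 1,
         monocyte = params$E0_frac)
}

# internal: noiseless lane trace + the quantities that produced it
lane_deterministic <- function(subject, stim, blot) {
  mult <- stimulation_multiplier(stim, subject$cell_type)
  ab <- effective_abundances(subject)
  amp <- blot$amplitude_per_unit * blot$protein_load_ug * ab * mult
  x <- seq_len(blot$migration_axis_length)
  centers <- c(MLH1 = blot$band_center_mlh1, MSH2 = blot$band_center_msh2)
  trace <- blot$background_level + blot$background_slope * (x - 1)
  for (p in names(centers))
    trace <- trace + amp[[p]] * exp(-(x - centers[[p]])^2 /
                                      (2 * blot$band_sigma^2))
  list(trace = trace, amplitudes = amp, abundances = ab, multiplier = mult)
}

# internal: one ground-truth row
truth_row <- function(subject, det, blot, seed) {
  ab <- det$abundances
  r <- if (max(ab) > 0 && min(ab) > 0) min(ab) / max(ab) else NA_real_
  data.frame(subject_id = subject$subject_id,
             cell_type = subject$cell_type,
             carrier_status = subject$carrier_status,
             dosage_factor = subject$dosage_factor,
             true_abundance_mlh1 = unname(ab["MLH1"]),
             true_abundance_msh2 = unname(ab["MSH2"]),
             stimulation_multiplier = det$multiplier,
             protein_load_ug = blot$protein_load_ug,
             true_target_ratio = r,
             seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Simulate a single lane profile
#'
#' Builds the noiseless trace (linear film background plus one Gaussian band
#' per protein, peak amplitude `amplitude_per_unit * protein_load_ug *
#' abundance * stimulation`), adds Gaussian noise, and records the generating
#' truth.
#'
#' @param subject a [subject_spec()].
#' @param stim a [stimulation_params()].
#' @param blot a [blot_config()].
#' @param seed integer seed for the noise (default: `blot$seed`).
#' @param lane_id lane identifier (default: the subject id).
#' @return list with elements `profile` (a [lane_profile()]) and `truth`
#'   (one-row data.frame).
#' @export
simulate_lane <- function(subject, stim, blot, seed = blot$seed,
                          lane_id = subject$subject_id) {
  stopifnot(inherits(subject, "subject_spec"),
            inherits(stim, "stimulation_params"),
            inherits(blot, "blot_config"))
  det <- lane_deterministic(subject, stim, blot)
  noisy <- withr::with_seed(seed,
    det$trace + stats::rnorm(length(det$trace), 0, blot$noise_sd))
  list(profile = lane_profile(seq_along(noisy), noisy, lane_id),
       truth = truth_row(subject, det, blot, seed))
}

# internal: normalize the `lanes` argument into a list of
# list(subject=, stim=, blot=) entries
normalize_lanes <- function(lanes, stim, blot) {
  if (inherits(lanes, "subject_spec")) lanes <- list(lanes)
  if (!length(lanes)) stop("at least one lane is required", call. = FALSE)
  lapply(lanes, function(ln) {
    if (inherits(ln, "subject_spec"))
      ln <- list(subject = ln)
    stopifnot(inherits(ln$subject, "subject_spec"))
    ln$stim <- ln$stim %||% stim
    ln$blot <- ln$blot %||% blot
    ln
  })
}

#' Simulate a multi-lane blot image
#'
#' Assembles per-lane profiles side by side into a 2-D grayscale image
#' (rows = migration axis, columns = lanes separated by background-only
#' gutters). The pixel value within a lane is the lane trace divided by the
#' lane width plus per-pixel noise of SD `noise_sd / sqrt(lane_width)`, so
#' the column-sum across a lane has the profile's noise SD. Lane boundary
#' metadata and the generating ground truth travel with the image.
#'
#' @param lanes a list whose elements are [subject_spec()]s or lists with
#'   elements `subject`, and optionally `stim` and `blot` (per-lane
#'   overrides, e.g. a different protein load per lane).
#' @param blot default [blot_config()] (geometry is taken from here and must
#'   be shared by all lanes).
#' @param stim default [stimulation_params()].
#' @param seed integer seed (default `blot$seed`); a fixed seed gives a
#'   bit-identical image on re-run.
#' @param gutter_px background-only pixels between lanes.
#' @return an object of class `blot_image`: list with `pixels` (matrix),
#'   `lanes` (data.frame: lane_id, col_start, col_end), `config`, `truth`.
#' @export
simulate_blot_image <- function(lanes, blot, stim = stimulation_params(),
                                seed = blot$seed, gutter_px = 4L) {
  stopifnot(inherits(blot, "blot_config"))
  lanes <- normalize_lanes(lanes, stim, blot)
  L <- blot$migration_axis_length
  w <- blot$lane_width
  n <- length(lanes)
  ncol_tot <- n * w + (n + 1L) * gutter_px
  det_img <- matrix(0, nrow = L, ncol = ncol_tot)
  bg_col <- (blot$background_level +
               blot$background_slope * (seq_len(L) - 1)) / w
  det_img[] <- bg_col  # recycled column-wise
  meta <- data.frame(lane_id = character(n), col_start = integer(n),
                     col_end = integer(n), stringsAsFactors = FALSE)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- lanes[[i]]
    if (ln$blot$migration_axis_length != L || ln$blot$lane_width != w)
      stop("all lanes must share the image geometry", call. = FALSE)
    det <- lane_deterministic(ln$subject, ln$stim, ln$blot)
    cs <- gutter_px + (i - 1L) * (w + gutter_px) + 1L
    det_img[, cs:(cs + w - 1L)] <- det$trace / w
    meta$lane_id[i] <- ln$lane_id %||% ln$subject$subject_id
    meta$col_start[i] <- cs
    meta$col_end[i] <- cs + w - 1L
    truth[[i]] <- truth_row(ln$subject, det, ln$blot, seed)
  }
  if (anyDuplicated(meta$lane_id))
    stop("lane ids must be unique", call. = FALSE)
  pixels <- withr::with_seed(seed,
    det_img + stats::rnorm(length(det_img), 0, blot$noise_sd / sqrt(w)))
  structure(list(pixels = pixels, lanes = meta, config = blot,
                 truth = do.call(rbind, truth)),
            class = "blot_image")
}

#' @export
print.blot_image <- function(x, ...) {
  cat(sprintf("<blot_image> %d x %d px, %d lanes (%s)\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$lanes),
              paste(utils::head(x$lanes$lane_id, 5), collapse = ", ")))
  invisible(x)
}

#' Simulate a protein-load dilution series
#'
#' One lane per load, same subject, everything else fixed: with zero noise
#' the net band integrals are exactly proportional to the loads. The
#' `"figure1b"` preset (see [mmr_preset()]) is calibrated so the smallest
#' load on the 2-fold grid 1.25-40 ug at which both bands pass the
#' detectability rule is 10 ug.
#'
#' @param blot a [blot_config()]; `protein_load_ug` is overridden per lane.
#' @param loads_ug vector of positive loads, one lane each.
#' @param subject the loaded sample (default: a cell line expressing both
#'   proteins at abundance 1, SW480-like).
#' @param stim a [stimulation_params()] (irrelevant for cell lines).
#' @param seed integer seed.
#' @return a `blot_image` whose `truth` carries one row per load; lane ids
#'   are `"load_<ug>"`.
#' @export
simulate_dilution_series <- function(blot, loads_ug,
                                     subject = subject_spec(
                                       "SW480", cell_type = "cell_line"),
                                     stim = stimulation_params(),
                                     seed = blot$seed) {
  if (!length(loads_ug) || !is.numeric(loads_ug) || any(loads_ug <= 0) ||
      anyNA(loads_ug))
    stop("loads_ug must be a non-empty vector of positive loads",
         call. = FALSE)
  lanes <- lapply(loads_ug, function(load) {
    b <- blot; b$protein_load_ug <- load
    list(subject = subject, stim = stim, blot = b,
         lane_id = sprintf("load_%g", load))
  })
  simulate_blot_image(lanes, blot, stim, seed = seed)
}

#' Simulate replicate ratio measurements for one subject
#'
#' Emulates repeated assay runs of the same sample. Two selectable routes:
#' \describe{
#'   \item{`"ratio"`}{direct ratio-noise model: each replicate draws the two
#'     band densities with independent multiplicative `N(0, cv^2)` errors
#'     around the subject's effective abundances and forms the min/max
#'     ratio. The Table 2 presets' `cv` values are calibrated in closed form
#'     so the expected replicate mean matches the corresponding
#'     reproducibility row (see [replicate_cv_for_mean()]).}
#'   \item{`"blot"`}{full round trip: each replicate jitters the band
#'     amplitudes by the same multiplicative error, simulates a noisy lane,
#'     and quantifies it through the densitometry stage.}
#' }
#'
#' @param subject a [subject_spec()].
#' @param n_reps number of replicates (>= 2, otherwise the replicate SD is
#'   undefined).
#' @param noise_preset preset name (e.g. `"table2-sw480"`, `"table2-wbc"`)
#'   or a list with elements `cv`, `blot`, `stim`.
#' @param seed integer seed; replicate `r` uses the child stream
#'   `child_seed(seed, paste0("rep-", r))`.
#' @param method `"ratio"` (default) or `"blot"`.
#' @return data.frame with columns replicate, mlh1_net, msh2_net, ratio,
#'   lower_protein.
#' @export
simulate_replicates <- function(subject, n_reps,
                                noise_preset = "table2-wbc",
                                seed = 1L,
                                method = c("ratio", "blot")) {
  stopifnot(inherits(subject, "subject_spec"))
  method <- match.arg(method)
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("n_reps must be >= 2 (replicate SD undefined otherwise)",
         call. = FALSE)
  n_reps <- as.integer(n_reps)
  np <- if (is.character(noise_preset)) mmr_preset(noise_preset) else
    noise_preset
  cv <- np$cv
  stopifnot(is.numeric(cv), cv >= 0)
  blot <- np$blot %||% blot_config()
  stim <- np$stim %||% stimulation_params()
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rows[[r]] <- withr::with_seed(child_seed(seed, paste0("rep-", r)), {
      eps <- stats::rnorm(2, 0, cv)
      if (method == "ratio") {
        ab <- effective_abundances(subject)
        scale <- 1000  # arbitrary density units
        m1 <- scale * ab[["MLH1"]] * max(0, 1 + eps[1])
        m2 <- scale * ab[["MSH2"]] * max(0, 1 + eps[2])
      } else {
        s2 <- subject
        s2$base_abundance_mlh1 <- subject$base_abundance_mlh1 *
          max(0, 1 + eps[1])
        s2$base_abundance_msh2 <- subject$base_abundance_msh2 *
          max(0, 1 + eps[2])
        sl <- simulate_lane(s2, stim, blot,
                            seed = child_seed(seed, paste0("lane-", r)))
        q <- quantify_lane(sl$profile, blot)
        m1 <- q$net[q$protein == "MLH1"]
        m2 <- q$net[q$protein == "MSH2"]
      }
      rr <- mmr_ratio(m1, m2, sample_id = subject$subject_id)
      data.frame(replicate = r, mlh1_net = m1, msh2_net = m2,
                 ratio = rr$ratio, lower_protein = rr$lower_protein,
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a screening cohort with known ground truth
#'
#' Draws each subject's carrier status, mutated gene, and true target MMR
#' ratio (truncated-normal components), then converts the ratio to protein
#' abundances: for carriers via the gene-dosage factor on the mutated
#' protein; for non-carriers via a small random imbalance of the base
#' abundances (which protein is lower is a fair coin flip, matching the
#' largely superimposable MLH1-lower / MSH2-lower subpopulations pooled in
#' the screening analysis).
#'
#' Subject `i` draws from the child stream `child_seed(seed, "subject-i")`,
#' so extending the cohort never changes earlier subjects.
#'
#' @param config a [cohort_config()].
#' @return an object of class `mmr_cohort`: list with `subjects` (list of
#'   [subject_spec()]), `truth` (data.frame with subject_id, carrier_status,
#'   mutated_gene, abundances, true_target_ratio), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  subjects <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    res <- withr::with_seed(child_seed(config$seed, paste0("subject-", i)), {
      id <- sprintf("S%03d", i)
      is_carrier <- stats::runif(1) < config$carrier_prevalence
      u_gene <- stats::runif(1)
      if (is_carrier) {
        gene <- if (u_gene < config$gene_split) "MLH1" else "MSH2"
        r <- rtruncnorm(1, config$carrier_ratio_mean,
                        config$carrier_ratio_sd, config$ratio_floor, 1)
        subj <- subject_spec(id, cell_type = "fresh_lymphocyte",
                             carrier_status = if (gene == "MLH1")
                               "mlh1_carrier" else "msh2_carrier",
                             dosage_factor = r)
      } else {
        gene <- NA_character_
        r <- rtruncnorm(1, config$noncarrier_ratio_mean,
                        config$noncarrier_ratio_sd, config$ratio_floor, 1)
        lower_mlh1 <- u_gene < 0.5  # which protein carries the imbalance
        subj <- subject_spec(id, cell_type = "fresh_lymphocyte",
                             carrier_status = "non_carrier",
                             base_abundance_mlh1 = if (lower_mlh1) r else 1,
                             base_abundance_msh2 = if (lower_mlh1) 1 else r)
      }
      ab <- effective_abundances(subj)
      list(subj = subj,
           row = data.frame(subject_id = id,
                            carrier_status = subj$carrier_status,
                            mutated_gene = gene,
                            true_abundance_mlh1 = unname(ab["MLH1"]),
                            true_abundance_msh2 = unname(ab["MSH2"]),
                            true_target_ratio = r,
                            stringsAsFactors = FALSE))
    })
    subjects[[i]] <- res$subj
    truth[[i]] <- res$row
  }
  structure(list(subjects = subjects, truth = do.call(rbind, truth),
                 config = config),
            class = "mmr_cohort")
}

#' @export
print.mmr_cohort <- function(x, ...) {
  tab <- table(x$truth$carrier_status)
  cat(sprintf("<mmr_cohort> %d subjects (%s), seed %d\n",
              nrow(x$truth),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$config$seed))
  invisible(x)
}
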