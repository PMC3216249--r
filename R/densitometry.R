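#' Extract a lane profile from a blot image
#'
#' The profile at each migration position is the column-sum of pixel
#' intensities across the lane's width, emulating film scanning followed by
#' lane highlighting.
#'
#' @param image a `blot_image` (see [simulate_blot_image()] or
#'   [read_blot_tiff()]).
#' @param lane_id lane identifier; must exist in the image metadata.
#' @return a [lane_profile()].
#' @export
extract_lane <- function(image, lane_id) {
  stopifnot(inherits(image, "blot_image"))
  i <- match(lane_id, image$lanes$lane_id)
  if (is.na(i))
    stop(sprintf("unknown lane_id '%s' (image has: %s)", lane_id,
                 paste(image$lanes$lane_id, collapse = ", ")), call. = FALSE)
  cols <- image$lanes$col_start[i]:image$lanes$col_end[i]
  v <- rowSums(image$pixels[, cols, drop = FALSE])
  lane_profile(seq_along(v), v, lane_id)
}

#' Locate a band's integration window in a lane profile
#'
#' The profile is detrended with a running-median baseline (window wide
#' enough not to follow a band), and the maximum of the detrended trace
#' within the search window is taken as the band center. The band SD is
#' estimated from the half-width at half-maximum and the returned window is
#' `center +/- round(k * sigma_est)`, clipped to the search window. If no
#' point in the search window rises above the detrended noise floor
#' (`noise_mult` robust SDs), the nominal window centered on the expected
#' position is returned with flag `"no_peak_found"`.
#'
#' @param profile a [lane_profile()].
#' @param protein `"MLH1"` or `"MSH2"` (carried through to the result).
#' @param search_window integer `c(start, end)`, 1-based inclusive pixel
#'   interval; must lie within the profile.
#' @param k window half-width in estimated band SDs (default 3).
#' @param sigma_default fallback band SD in pixels when no peak is found or
#'   the width estimate is degenerate.
#' @param noise_mult robust-SD multiple defining the detrended noise floor.
#' @return list with elements `protein`, `start`, `end`, `center`,
#'   `sigma_est`, `flags` (character vector, possibly empty).
#' @export
locate_band <- function(profile, protein = c("MLH1", "MSH2"), search_window,
                        k = 3, sigma_default = 4, noise_mult = 3) {
  stopifnot(inherits(profile, "lane_profile"))
  protein <- match.arg(protein)
  pos <- profile$positions
  sw <- as.integer(round(search_window))
  if (length(sw) != 2L || sw[1] > sw[2] || sw[1] < min(pos) || sw[2] > max(pos))
    stop("search_window must be an interval inside the profile",
         call. = FALSE)
  y <- profile$intensities
  k_med <- min(2L * ceiling(6 * sigma_default) + 1L,
               if (length(y) %% 2L == 1L) length(y) else length(y) - 1L)
  baseline <- stats::runmed(y, k_med, endrule = "median")
  det <- y - baseline
  in_sw <- pos >= sw[1] & pos <= sw[2]
  floor_lvl <- noise_mult * stats::mad(det)
  flags <- character(0)
  if (!any(in_sw) || max(det[in_sw]) <= floor_lvl || max(det[in_sw]) <= 0) {
    center <- as.integer(round(mean(sw)))
    sigma_est <- sigma_default
    flags <- "no_peak_found"
  } else {
    center <- pos[in_sw][which.max(det[in_sw])]
    peak <- det[pos == center]
    half <- peak / 2
    # half-width at half-maximum, each side, within the search window;
    # the crossing is interpolated between pixels so the width estimate is
    # not biased low by the integer grid
    idx_c <- which(pos == center)
    right <- idx_c
    while (right < length(pos) && pos[right + 1L] <= sw[2] &&
           det[right + 1L] >= half) right <- right + 1L
    left <- idx_c
    while (left > 1L && pos[left - 1L] >= sw[1] &&
           det[left - 1L] >= half) left <- left - 1L
    frac_beyond <- function(i, step) {
      j <- i + step
      if (j < 1L || j > length(pos) || pos[j] < sw[1] || pos[j] > sw[2])
        return(0)
      drop <- det[i] - det[j]
      if (drop <= 0) return(0)
      min(1, max(0, (det[i] - half) / drop))
    }
    hw_r <- (pos[right] - center) + frac_beyond(right, 1L)
    hw_l <- (center - pos[left]) + frac_beyond(left, -1L)
    hwhm <- (hw_r + hw_l) / 2
    sigma_est <- hwhm / sqrt(2 * log(2))
    if (!is.finite(sigma_est) || sigma_est < 1)
      sigma_est <- sigma_default
    sigma_est <- min(sigma_est, 2 * sigma_default)
  }
  half_w <- as.integer(round(k * sigma_est))
  list(protein = protein,
       start = max(sw[1], center - half_w),
       end = min(sw[2], center + half_w),
       center = center, sigma_est = sigma_est, flags = flags)
}

#' Measure a band: integration and equivalent-area background subtraction
#'
#' Raw density is the summed intensity over the integration window. The
#' background is estimated from flanking pixels in the same lane (the same
#' film area): the nearest pixels beyond a small guard gap on each side of
#' the window — excluding any other band windows — are collected, an equal
#' count per side up to half the window width, and the background density
#' is the mean of the two side medians times the window width. This
#' equivalent-area estimate cancels a constant offset identically and, with
#' balanced sides, a linear ramp exactly. Net density is raw minus
#' background and is never clamped: negative values are kept and simply
#' fail the detectability rule.
#'
#' A band is called detectable when `net >= lod_abs` and
#' `net >= lod_snr * sd(flank) * sqrt(window width)` (absolute floor plus
#' signal-to-noise multiple). Defaults are co-calibrated with the default
#' [blot_config()] amplitude scale.
#'
#' @param profile a [lane_profile()].
#' @param window integer `c(start, end)`, 1-based inclusive, inside the
#'   profile and not overlapping any `exclude` window.
#' @param protein optional label carried into the result.
#' @param lod_abs absolute net-density floor.
#' @param lod_snr signal-to-noise multiple.
#' @param exclude list of windows (integer pairs) excluded from the flanks,
#'   typically the other protein's band window.
#' @param flank_gap pixels skipped between the window edge and the first
#'   flank pixel, so the band's skirt does not inflate the background
#'   (default 4, about one band SD).
#' @param sat_level optional saturation intensity; any in-window value at or
#'   above it adds a `"saturated"` flag (no correction is applied).
#' @return an object of class `band_measurement`: list with `protein`,
#'   `window`, `raw_density`, `background_density`, `net_density`,
#'   `detectable`, `flank_sd`, `flags`.
#' @export
measure_band <- function(profile, window, protein = NA_character_,
                         lod_abs = 300, lod_snr = 3, exclude = list(),
                         flank_gap = 4L, sat_level = NULL) {
  stopifnot(inherits(profile, "lane_profile"))
  pos <- profile$positions
  w <- as.integer(round(window))
  if (length(w) != 2L || w[1] > w[2] || w[1] < min(pos) || w[2] > max(pos))
    stop("window must be an interval inside the profile", call. = FALSE)
  for (ex in exclude) {
    if (w[1] <= ex[2] && ex[1] <= w[2])
      stop("band window overlaps a flank exclusion zone", call. = FALSE)
  }
  in_w <- pos >= w[1] & pos <= w[2]
  W <- sum(in_w)
  excluded <- rep(FALSE, length(pos))
  for (ex in exclude) excluded <- excluded | (pos >= ex[1] & pos <= ex[2])
  cand <- which(!in_w & !excluded)
  # nearest flanking pixels beyond the guard gap, an equivalent half-width
  # per side; averaging the two side medians cancels a linear background
  # even when the sides end up unequal (edge of film, excluded band)
  dist <- pmax(w[1] - pos[cand], pos[cand] - w[2])
  cand <- cand[dist > flank_gap]
  dist <- dist[dist > flank_gap]
  n_half <- ceiling(W / 2)
  side_sel <- function(side, n) {
    s <- cand[side]
    s[order(dist[side])][seq_len(min(n, length(s)))]
  }
  is_left <- pos[cand] < w[1]
  # equal counts per side keep the two side medians symmetric about the
  # window, so a linear ramp cancels exactly in their average
  n_bal <- min(n_half, sum(is_left), sum(!is_left))
  if (n_bal >= 1L) {
    left <- side_sel(is_left, n_bal)
    right <- side_sel(!is_left, n_bal)
  } else {
    left <- side_sel(is_left, W)
    right <- side_sel(!is_left, W)
  }
  flank <- c(left, right)
  flags <- character(0)
  if (length(flank) < W) flags <- c(flags, "short_flank")
  y <- profile$intensities
  raw <- sum(y[in_w])
  side_medians <- c(if (length(left)) stats::median(y[left]),
                    if (length(right)) stats::median(y[right]))
  bg <- if (length(side_medians)) mean(side_medians) * W else 0
  flank_sd <- if (length(flank) >= 2L) stats::sd(y[flank]) else 0
  net <- raw - bg
  if (!is.null(sat_level) && any(y[in_w] >= sat_level))
    flags <- c(flags, "saturated")
  detectable <- isTRUE(net >= lod_abs && net >= lod_snr * flank_sd * sqrt(W))
  structure(list(protein = protein, window = w, raw_density = raw,
                 background_density = bg, net_density = net,
                 detectable = detectable, flank_sd = flank_sd,
                 flags = flags),
            class = "band_measurement")
}

#' @export
print.band_measurement <- function(x, ...) {
  cat(sprintf(
    "<band_measurement> %s [%d, %d]: raw %.4g, bg %.4g, net %.4g, %s%s\n",
    x$protein, x$window[1], x$window[2], x$raw_density,
    x$background_density, x$net_density,
    if (x$detectable) "detectable" else "not detectable",
    if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ","), ")")
    else ""))
  invisible(x)
}

# internal: search windows for the two bands, disjoint by construction
band_search_windows <- function(blot, margin = 6L) {
  L <- blot$migration_axis_length
  half <- ceiling(3 * blot$band_sigma) + margin
  mid <- (blot$band_center_msh2 + blot$band_center_mlh1) / 2
  lo_c <- min(blot$band_center_msh2, blot$band_center_mlh1)
  hi_c <- max(blot$band_center_msh2, blot$band_center_mlh1)
  sw <- list(
    MSH2 = c(max(1, round(blot$band_center_msh2 - half)),
             min(L, round(blot$band_center_msh2 + half))),
    MLH1 = c(max(1, round(blot$band_center_mlh1 - half)),
             min(L, round(blot$band_center_mlh1 + half))))
  # keep the two searches on their own sides of the midpoint
  for (p in names(sw)) {
    ctr <- if (p == "MSH2") blot$band_center_msh2 else blot$band_center_mlh1
    if (ctr <= mid) sw[[p]][2] <- min(sw[[p]][2], floor(mid) - 1)
    else sw[[p]][1] <- max(sw[[p]][1], ceiling(mid) + 1)
  }
  sw
}

#' Quantify both MMR bands in one lane profile
#'
#' Locates and measures the MLH1 and MSH2 bands using search windows derived
#' from the blot geometry, excluding each band's window from the other's
#' background flanks.
#'
#' @param profile a [lane_profile()].
#' @param blot a [blot_config()] supplying band centers and sigma.
#' @param lod_abs,lod_snr detectability thresholds (see [measure_band()]).
#' @param k integration half-width in band SDs.
#' @return data.frame with one row per protein: protein, window_start,
#'   window_end, center, sigma_est, raw, background, net, detectable, flags.
#' @export
quantify_lane <- function(profile, blot, lod_abs = 300, lod_snr = 3, k = 3) {
  stopifnot(inherits(blot, "blot_config"))
  sw <- band_search_windows(blot)
  loc <- lapply(c("MLH1", "MSH2"), function(p)
    locate_band(profile, p, sw[[p]], k = k,
                sigma_default = blot$band_sigma))
  names(loc) <- c("MLH1", "MSH2")
  rows <- lapply(c("MLH1", "MSH2"), function(p) {
    other <- setdiff(c("MLH1", "MSH2"), p)
    win <- c(loc[[p]]$start, loc[[p]]$end)
    # exclusion covers the other band's window plus its skirt
    m <- measure_band(profile, win, protein = p, lod_abs = lod_abs,
                      lod_snr = lod_snr,
                      exclude = list(c(loc[[other]]$start - 4L,
                                       loc[[other]]$end + 4L)))
    data.frame(protein = p, window_start = win[1], window_end = win[2],
               center = loc[[p]]$center, sigma_est = loc[[p]]$sigma_est,
               raw = m$raw_density, background = m$background_density,
               net = m$net_density, detectable = m$detectable,
               flags = paste(c(loc[[p]]$flags, m$flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify all samples on a blot
#'
#' Runs extract -> locate -> measure for both proteins in every manifest
#' lane, producing a tidy table with one row per (sample, protein).
#'
#' @param x a `blot_image`, or a list of [lane_profile()]s (named by lane id
#'   or carrying their own `lane_id`).
#' @param manifest data.frame with columns `sample_id`, `lane_id`; default
#'   is one sample per lane, sample id equal to lane id. An empty manifest
#'   yields an empty table.
#' @param blot a [blot_config()]; defaults to `x$config` for images.
#' @param lod_abs,lod_snr detectability thresholds.
#' @return data.frame: sample_id, lane_id, protein, window_start,
#'   window_end, center, sigma_est, raw, background, net, detectable, flags.
#' @export
quantify_sample <- function(x, manifest = NULL, blot = NULL,
                            lod_abs = 300, lod_snr = 3) {
  if (inherits(x, "blot_image")) {
    blot <- blot %||% x$config
    lane_ids <- x$lanes$lane_id
    get_profile <- function(id) extract_lane(x, id)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "lane_profile"))) {
    if (is.null(blot))
      stop("a blot_config is required when quantifying bare profiles",
           call. = FALSE)
    lane_ids <- vapply(x, function(p) p$lane_id, "")
    names(x) <- lane_ids
    get_profile <- function(id) x[[id]]
  } else stop("x must be a blot_image or a list of lane_profile objects",
              call. = FALSE)
  if (is.null(manifest))
    manifest <- data.frame(sample_id = lane_ids, lane_id = lane_ids,
                           stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest),
            all(c("sample_id", "lane_id") %in% names(manifest)))
  if (!nrow(manifest)) {
    return(data.frame(sample_id = character(0), lane_id = character(0),
                      protein = character(0), window_start = integer(0),
                      window_end = integer(0), center = integer(0),
                      sigma_est = numeric(0), raw = numeric(0),
                      background = numeric(0), net = numeric(0),
                      detectable = logical(0), flags = character(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(manifest$lane_id, lane_ids)
  if (length(missing))
    stop("manifest lanes not present on the blot: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    q <- quantify_lane(get_profile(manifest$lane_id[i]), blot,
                       lod_abs = lod_abs, lod_snr = lod_snr)
    cbind(data.frame(sample_id = manifest$sample_id[i],
                     lane_id = manifest$lane_id[i],
                     stringsAsFactors = FALSE), q)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection limit of a dilution series
#'
#' Quantifies every lane of a dilution-series blot and reports the smallest
#' protein load at which both bands are called detectable.
#'
#' @param series a `blot_image` from [simulate_dilution_series()] (its
#'   `truth` table carries the per-lane loads).
#' @param lod_abs,lod_snr detectability thresholds.
#' @return list with `limit_ug` (smallest load with both bands detectable,
#'   or `NA` if none) and `table` (per-load detectability).
#' @export
detection_limit <- function(series, lod_abs = 300, lod_snr = 3) {
  stopifnot(inherits(series, "blot_image"))
  q <- quantify_sample(series, lod_abs = lod_abs, lod_snr = lod_snr)
  loads <- series$truth$protein_load_ug
  names(loads) <- series$truth$subject_id
  # lane ids were assigned per load by simulate_dilution_series
  lane_loads <- series$truth$protein_load_ug[
    match(q$lane_id, series$lanes$lane_id)]
  both <- tapply(q$detectable, lane_loads, all)
  tab <- data.frame(load_ug = as.numeric(names(both)),
                    both_detectable = as.logical(both))
  tab <- tab[order(tab$load_ug), , drop = FALSE]
  rownames(tab) <- NULL
  ok <- tab$load_ug[tab$both_detectable]
  list(limit_ug = if (length(ok)) min(ok) else NA_real_, table = tab)
}

#' Lane-profile CSV I/O
#'
#' Long-format CSV with columns `lane_id`, `position`, `intensity`
#' (UTF-8, `.` decimal), the interchange format for pre-extracted
#' densitometry traces.
#'
#' @param profiles a list of [lane_profile()]s.
#' @param path CSV file path.
#' @return `write_profiles_csv` returns the path invisibly;
#'   `read_profiles_csv` returns a named list of [lane_profile()]s.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "lane_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(lane_id = p$lane_id, position = p$positions,
               intensity = p$intensities, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lane_id", "position", "intensity") %in% names(df)))
  ids <- unique(df$lane_id)
  out <- lapply(ids, function(id) {
    d <- df[df$lane_id == id, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    lane_profile(d$position, d$intensity, id)
  })
  stats::setNames(out, ids)
}
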