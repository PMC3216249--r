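test_that("extract_lane recovers profiles and flat lanes", {
  blot <- noiseless_blot()
  subj <- subject_spec("A", cell_type = "cell_line")
  img <- simulate_blot_image(list(subj), blot)
  ref <- simulate_lane(subj, stimulation_params(), blot)
  expect_equal(extract_lane(img, "A")$intensities,
               ref$profile$intensities, tolerance = 1e-10)
  expect_error(extract_lane(img, "nope"), "unknown lane_id")

  # hand-built image: uniform intensity c over a lane of width w sums to c*w
  flat <- structure(list(
    pixels = matrix(2.5, nrow = 30, ncol = 12),
    lanes = data.frame(lane_id = "L1", col_start = 3L, col_end = 10L),
    config = blot, truth = NULL), class = "blot_image")
  expect_equal(extract_lane(flat, "L1")$intensities, rep(2.5 * 8, 30))
})

test_that("locate_band finds peaks and degrades gracefully", {
  x <- 1:120
  y <- 40 * exp(-(x - 80)^2 / (2 * 16))  # sigma 4, centered at 80
  prof <- lane_profile(x, y, "L")
  loc <- locate_band(prof, "MLH1", c(62, 98))
  expect_equal(loc$center, 80)
  expect_length(loc$flags, 0)
  expect_equal(loc$sigma_est, 4, tolerance = 0.35)

  flat <- lane_profile(x, rep(5, 120), "F")
  locf <- locate_band(flat, "MLH1", c(62, 98), sigma_default = 4)
  expect_identical(locf$flags, "no_peak_found")
  expect_equal(locf$center, 80)
  expect_equal(c(locf$start, locf$end), c(68, 92))

  expect_error(locate_band(prof, "MLH1", c(100, 130)), "inside")
})

test_that("locate_band keeps the two band windows apart", {
  blot <- noiseless_blot()
  sl <- simulate_lane(subject_spec("A", cell_type = "cell_line"),
                      stimulation_params(), blot)
  q <- quantify_lane(sl$profile, blot)
  msh2 <- q[q$protein == "MSH2", ]
  mlh1 <- q[q$protein == "MLH1", ]
  expect_lt(msh2$window_end, mlh1$window_start)
  expect_equal(msh2$center, blot$band_center_msh2)
  expect_equal(mlh1$center, blot$band_center_mlh1)
})

test_that("measure_band implements equivalent-area subtraction", {
  x <- 1:200
  # flat profile: raw equals background exactly, net 0, not detectable
  flat <- lane_profile(x, rep(7, 200), "F")
  m <- measure_band(flat, c(50, 80))
  expect_equal(m$raw_density, 7 * 31)
  expect_equal(m$background_density, 7 * 31)
  expect_equal(m$net_density, 0)
  expect_false(m$detectable)

  # noiseless Gaussian on zero background: closed-form area oracle
  A <- 10; mu <- 100; sig <- 5
  g <- lane_profile(x, A * exp(-(x - mu)^2 / (2 * sig^2)), "G")
  w <- c(mu - 4 * sig, mu + 4 * sig)
  mg <- measure_band(g, w, lod_abs = 1e-6)
  oracle <- gaussian_area(A, mu, sig, w[1] - 0.5, w[2] + 0.5)
  expect_equal(mg$net_density, oracle, tolerance = 1e-4)
  expect_true(mg$detectable)

  # windows may not intrude into declared exclusion zones
  expect_error(measure_band(g, w, exclude = list(c(115, 140))),
               "exclusion zone")
})

test_that("constant offsets cancel exactly and net is monotone in amplitude", {
  x <- 1:120
  base <- 30 * exp(-(x - 60)^2 / 32)
  for (offset in c(0, 13.7, 200)) {
    m <- measure_band(lane_profile(x, base + offset, "L"), c(48, 72),
                      lod_abs = 1e-6)
    m0 <- measure_band(lane_profile(x, base, "L"), c(48, 72),
                       lod_abs = 1e-6)
    expect_equal(m$net_density, m0$net_density)  # exact cancellation
  }
  # monotonicity under fixed noise realization
  noise <- withr::with_seed(4, rnorm(120, 0, 2))
  nets <- vapply(seq(5, 50, by = 5), function(A) {
    prof <- lane_profile(x, A * exp(-(x - 60)^2 / 32) + noise, "L")
    measure_band(prof, c(48, 72), lod_abs = 1e-6)$net_density
  }, 0)
  expect_true(all(diff(nets) > 0))
})

test_that("saturated pixels are flagged", {
  x <- 1:120
  y <- 70000 * exp(-(x - 60)^2 / 32)
  m <- measure_band(lane_profile(x, pmin(y, 65535), "L"), c(48, 72),
                    sat_level = 65535)
  expect_true("saturated" %in% m$flags)
})

test_that("the dilution preset reproduces the 10 ug detection limit", {
  p <- mmr_preset("figure1b")
  ser <- simulate_dilution_series(p$blot, p$loads_ug, p$subject, p$stim)
  q <- quantify_sample(ser, lod_abs = p$lod_abs, lod_snr = p$lod_snr)
  det_at <- function(load)
    q$detectable[q$lane_id == sprintf("load_%g", load)]
  expect_false(all(det_at(5)))   # at least one band missed at 5 ug
  expect_true(all(det_at(10)))   # both called at 10 ug
  dl <- detection_limit(ser, p$lod_abs, p$lod_snr)
  expect_identical(dl$limit_ug, 10)
  expect_identical(dl$table$both_detectable, c(FALSE, FALSE, FALSE, TRUE,
                                               TRUE, TRUE))
})

test_that("quantify_sample handles manifests and control panels", {
  blot <- blot_config(seed = 21L)
  img <- simulate_blot_image(control_panel(), blot)
  q <- quantify_sample(img)
  det <- function(lane, prot)
    q$detectable[q$lane_id == lane & q$protein == prot]
  expect_true(det("SW480", "MLH1") && det("SW480", "MSH2"))
  expect_true(!det("HCT116", "MLH1") && det("HCT116", "MSH2"))
  expect_true(det("LoVo", "MLH1") && !det("LoVo", "MSH2"))

  empty <- quantify_sample(img, manifest = data.frame(
    sample_id = character(0), lane_id = character(0)))
  expect_identical(nrow(empty), 0L)

  expect_error(quantify_sample(img, manifest = data.frame(
    sample_id = "x", lane_id = "missing_lane")), "missing_lane")
})

test_that("lane profiles round-trip through CSV", {
  blot <- blot_config(seed = 9L)
  img <- simulate_blot_image(control_panel(), blot)
  profs <- lapply(img$lanes$lane_id, function(id) extract_lane(img, id))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(profs, path)
  back <- read_profiles_csv(path)
  expect_identical(names(back), img$lanes$lane_id)
  expect_equal(back$SW480$intensities, profs[[1]]$intensities,
               tolerance = 1e-12)
  # quantification from the re-imported profiles matches the image route
  q1 <- quantify_sample(img)
  q2 <- quantify_sample(unname(back), blot = blot)
  expect_equal(q2$net, q1$net, tolerance = 1e-9)
  expect_identical(q2$detectable, q1$detectable)
})

test_that("a full synthetic cohort quantifies cleanly", {
  pc <- mmr_preset("figure3")
  cc <- pc$cohort
  cc$seed <- 31L
  res <- process_cohort(cc, pc$blot, pc$stim)
  q <- res$measurements
  expect_identical(nrow(q), 100L)  # 50 lanes x 2 proteins
  # per-lane integration windows never overlap
  for (id in unique(q$lane_id)) {
    rows <- q[q$lane_id == id, ]
    expect_lt(rows$window_end[rows$protein == "MSH2"],
              rows$window_start[rows$protein == "MLH1"])
  }
})

test_that("noiseless round trip recovers the true abundance ratio", {
  pc <- mmr_preset("figure3")
  cc <- pc$cohort
  cc$n_subjects <- 12L
  cc$seed <- 17L
  res <- process_cohort(cc, noiseless_blot(), pc$stim)
  rel_err <- abs(res$ratios$ratio - res$ratios$true_target_ratio) /
    res$ratios$true_target_ratio
  expect_true(all(rel_err < 1e-3))
})

test_that("noiseless band measurements match the Gaussian area oracle", {
  blot <- noiseless_blot()
  stim <- stimulation_params()
  mult <- stimulation_multiplier(stim, "fresh_lymphocyte")
  subj <- subject_spec("S", carrier_status = "mlh1_carrier",
                       dosage_factor = 0.7)
  sl <- simulate_lane(subj, stim, blot)
  q <- quantify_lane(sl$profile, blot, lod_abs = 1e-6)
  for (p in c("MLH1", "MSH2")) {
    ab <- if (p == "MLH1") 0.7 else 1
    A <- blot$amplitude_per_unit * blot$protein_load_ug * ab * mult
    ctr <- if (p == "MLH1") blot$band_center_mlh1 else blot$band_center_msh2
    row <- q[q$protein == p, ]
    oracle <- gaussian_area(A, ctr, blot$band_sigma,
                            row$window_start - 0.5, row$window_end + 0.5)
    expect_lt(abs(row$net - oracle) / oracle, 1e-3)
  }
})
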