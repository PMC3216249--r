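test_that("stimulation multiplier follows the dose/time/cell-type model", {
  sp <- stimulation_params(pha_dose = 10, time_hr = 48, K_d = 5, tau = 24,
                           E0_frac = 0.05)
  # hand-evaluated closed form: E0 + 0.95 * (10/15) * (1 - e^-2)
  expect_equal(stimulation_multiplier(sp, "fresh_lymphocyte"),
               0.05 + 0.95 * (2 / 3) * (1 - exp(-2)))
  # zero dose leaves fresh cells at baseline
  expect_equal(stimulation_multiplier(
    stimulation_params(pha_dose = 0, time_hr = 48), "fresh_lymphocyte"),
    0.05)
  # immortalized cells are insensitive to dose
  expect_identical(
    stimulation_multiplier(stimulation_params(pha_dose = 0),
                           "immortalized_lymphocyte"),
    stimulation_multiplier(stimulation_params(pha_dose = 10),
                           "immortalized_lymphocyte"))
  expect_identical(stimulation_multiplier(sp, "cell_line"), 1)
  # monocytes stay at baseline at any dose/time
  expect_equal(stimulation_multiplier(
    stimulation_params(pha_dose = 40, time_hr = 96), "monocyte"), 0.05)
  expect_error(stimulation_params(pha_dose = -1), "pha_dose")
  expect_error(stimulation_params(time_hr = -5), "time_hr")
})

test_that("stimulation multiplier is monotone and bounded", {
  doses <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  times <- c(0, 6, 12, 24, 48, 96)
  for (ct in c("fresh_lymphocyte", "immortalized_lymphocyte", "monocyte")) {
    m <- outer(doses, times, Vectorize(function(d, t)
      stimulation_multiplier(stimulation_params(pha_dose = d, time_hr = t),
                             ct)))
    expect_true(all(m >= 0.05 - 1e-12 & m <= 1))
    expect_true(all(diff(m) >= -1e-12))        # non-decreasing in dose
    expect_true(all(t(diff(t(m))) >= -1e-12))  # non-decreasing in time
    if (ct != "fresh_lymphocyte")
      expect_true(all(m == m[1, 1]))           # flat response
  }
})

test_that("simulate_lane matches its stated construction", {
  blot <- noiseless_blot()
  stim <- stimulation_params()
  # symmetric subject: equal peak heights at the two centers
  sl <- simulate_lane(subject_spec("A", cell_type = "cell_line"),
                      stim, blot)
  y <- sl$profile$intensities
  bg <- blot$background_level +
    blot$background_slope * (sl$profile$positions - 1)
  peaks <- (y - bg)[c(blot$band_center_msh2, blot$band_center_mlh1)]
  expect_equal(peaks[1], peaks[2], tolerance = 1e-10)

  # doubling protein load doubles both net integrals
  blot2 <- noiseless_blot(protein_load_ug = 20)
  sl2 <- simulate_lane(subject_spec("A", cell_type = "cell_line"),
                       stim, blot2)
  for (p in c("MLH1", "MSH2"))
    expect_equal(net_integral_direct(sl2$profile, blot2, p),
                 2 * net_integral_direct(sl$profile, blot, p),
                 tolerance = 1e-10)

  # heterozygote dosage halves the mutated protein's band area exactly
  car <- simulate_lane(subject_spec("C", cell_type = "cell_line",
                                    carrier_status = "mlh1_carrier",
                                    dosage_factor = 0.5), stim, blot)
  expect_equal(net_integral_direct(car$profile, blot, "MLH1"),
               0.5 * net_integral_direct(car$profile, blot, "MSH2"),
               tolerance = 1e-6)
  expect_equal(car$truth$true_target_ratio, 0.5)
  # and the band area agrees with the closed-form Gaussian oracle
  A <- blot$amplitude_per_unit * blot$protein_load_ug * 0.5
  expect_equal(net_integral_direct(car$profile, blot, "MLH1"),
               gaussian_area(A, blot$band_center_mlh1, blot$band_sigma,
                             blot$band_center_mlh1 - 12.5,
                             blot$band_center_mlh1 + 12.5),
               tolerance = 1e-4)
})

test_that("blot images assemble lanes faithfully and deterministically", {
  blot <- noiseless_blot()
  subj <- subject_spec("A", cell_type = "cell_line")
  img <- simulate_blot_image(list(subj), blot)
  prof <- extract_lane(img, "A")
  ref <- simulate_lane(subj, stimulation_params(), blot)
  expect_equal(prof$intensities, ref$profile$intensities,
               tolerance = 1e-10)

  noisy <- blot_config(seed = 11L)
  img1 <- simulate_blot_image(control_panel(), noisy)
  img2 <- simulate_blot_image(control_panel(), noisy)
  expect_identical(img1$pixels, img2$pixels)  # fixed seed, bit-identical
  img3 <- simulate_blot_image(control_panel(), noisy, seed = 12L)
  expect_false(identical(img1$pixels, img3$pixels))

  expect_error(simulate_blot_image(list(), blot), "at least one lane")
  bad <- list(subject_spec("B", cell_type = "cell_line"))
  bad[[1]] <- list(subject = bad[[1]],
                   blot = blot_config(migration_axis_length = 90L))
  expect_error(simulate_blot_image(bad, blot), "geometry")
})

test_that("band windows must not overlap", {
  expect_error(blot_config(band_center_msh2 = 60, band_center_mlh1 = 70,
                           band_sigma = 4), "overlap")
})

test_that("dilution series is linear in load", {
  blot <- noiseless_blot()
  ser <- simulate_dilution_series(blot, c(10, 20, 40))
  ints <- vapply(ser$lanes$lane_id, function(id)
    net_integral_direct(extract_lane(ser, id), blot, "MLH1"), 0)
  expect_equal(unname(ints / ints[1]), c(1, 2, 4), tolerance = 1e-8)
  one <- simulate_dilution_series(blot, 5)
  expect_identical(nrow(one$lanes), 1L)
  expect_error(simulate_dilution_series(blot, numeric(0)), "positive")
  expect_error(simulate_dilution_series(blot, c(10, -1)), "positive")
})

test_that("replicate simulation honours its noise and seed contracts", {
  subj <- subject_spec("S", cell_type = "cell_line")
  silent <- list(cv = 0, blot = blot_config(noise_sd = 0))
  reps <- simulate_replicates(subj, 5, silent, seed = 3)
  expect_true(all(reps$ratio == reps$ratio[1]))  # no noise, no spread
  expect_error(simulate_replicates(subj, 1, "table2-sw480"), "n_reps")

  a <- simulate_replicates(subj, 4, "table2-sw480", seed = 1)
  b <- simulate_replicates(subj, 4, "table2-sw480", seed = 2)
  expect_false(any(a$ratio == b$ratio))
  expect_identical(a, simulate_replicates(subj, 4, "table2-sw480",
                                          seed = 1))

  # reproducibility preset recovers its encoded mean
  means <- vapply(1:80, function(s)
    mean(simulate_replicates(subj, 6, "table2-sw480", seed = s)$ratio), 0)
  expect_equal(mean(means), 0.989, tolerance = 0.003)
})

test_that("blot-route replicates fall inside the reproducibility bands", {
  bands <- list("table2-sw480" = c(0.983, 0.995),
                "table2-wbc1" = c(0.962, 0.998),
                "table2-wbc4" = c(0.847, 0.995))
  for (nm in names(bands)) {
    pr <- mmr_preset(nm)
    m <- mean(vapply(1:20, function(s)
      mean(simulate_replicates(pr$subject, 6, nm, seed = s,
                               method = "blot")$ratio), 0))
    expect_gt(m, bands[[nm]][1])
    expect_lt(m, bands[[nm]][2])
  }
})

test_that("cohort generation matches its configuration", {
  none <- simulate_cohort(cohort_config(n_subjects = 40,
                                        carrier_prevalence = 0, seed = 5))
  expect_true(all(none$truth$carrier_status == "non_carrier"))
  expect_true(all(none$truth$true_target_ratio > 0.85))  # nc component

  allc <- simulate_cohort(cohort_config(n_subjects = 20,
                                        carrier_prevalence = 1,
                                        carrier_ratio_sd = 0, seed = 5))
  expect_true(all(allc$truth$carrier_status != "non_carrier"))
  expect_true(all(allc$truth$true_target_ratio == 0.81))

  expect_error(cohort_config(carrier_prevalence = 1.2), "carrier_prevalence")
  expect_error(cohort_config(carrier_ratio_mean = 0.99), "below")
})

test_that("cohort subjects use stable per-subject seed streams", {
  small <- simulate_cohort(cohort_config(n_subjects = 15, seed = 9))
  large <- simulate_cohort(cohort_config(n_subjects = 25, seed = 9))
  expect_identical(small$truth, large$truth[1:15, ])
  expect_identical(small$truth,
                   simulate_cohort(cohort_config(n_subjects = 15,
                                                 seed = 9))$truth)
})

test_that("cohort carrier fraction converges to the prevalence", {
  big <- simulate_cohort(cohort_config(n_subjects = 10000, seed = 2))
  frac <- mean(big$truth$carrier_status != "non_carrier")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
  # ratios respect the truncation floor and the unit ceiling
  expect_true(all(big$truth$true_target_ratio >= 0.3 &
                    big$truth$true_target_ratio <= 1))
})
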