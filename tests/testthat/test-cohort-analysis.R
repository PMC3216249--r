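test_that("ratio histogram uses right-closed bins over (0, 1]", {
  h <- ratio_histogram(rep(1.0, 7), bin_width = 0.05)
  expect_identical(sum(h$count), 7L)
  occupied <- h[h$count > 0, ]
  expect_identical(nrow(occupied), 1L)
  expect_equal(c(occupied$bin_lo, occupied$bin_hi), c(0.95, 1.0))

  # boundary value falls in the bin it closes
  h2 <- ratio_histogram(c(0.05, 0.0500001), bin_width = 0.05)
  expect_identical(h2$count[1], 1L)
  expect_identical(h2$count[2], 1L)

  expect_identical(nrow(ratio_histogram(numeric(0))), 0L)
  expect_identical(nrow(ratio_histogram(NA_real_)), 0L)
  expect_error(ratio_histogram(c(0.5), bin_width = 0), "positive")
  expect_error(ratio_histogram(c(1.5)), "lie in")
})

test_that("k=1 fit is the closed-form Gaussian MLE", {
  x <- withr::with_seed(8, rnorm(40, 0.9, 0.05))
  fit <- fit_mixture(x, k = 1)
  expect_equal(fit$means, mean(x))
  expect_equal(fit$sds, sqrt(mean((x - mean(x))^2)))  # ML, n denominator
  expect_equal(fit$loglik, sum(dnorm(x, fit$means, fit$sds, log = TRUE)))
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(40))
  expect_true(fit$converged)
})

test_that("k=2 fit separates two point masses", {
  x <- c(rep(0.5, 15), rep(0.9, 15))
  fit <- fit_mixture(x, k = 2, seed = 1)
  expect_equal(fit$means, c(0.9, 0.5), tolerance = 1e-6)  # sorted descending
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_true(all(fit$sds >= 1e-3))  # SD floor prevents degenerate spikes
  expect_error(fit_mixture(x[1:8], k = 2), "too few")
  expect_error(fit_mixture(x, k = 3), "k must be")
})

test_that("EM log-likelihood trace is non-decreasing", {
  for (s in 1:5) {
    x <- withr::with_seed(s, c(rnorm(40, 0.97, 0.02), rnorm(12, 0.8, 0.07)))
    fit <- fit_mixture(x, k = 2, seed = s)
    expect_true(all(diff(fit$trace) >= -1e-9 * (1 + abs(fit$loglik))))
  }
})

test_that("component labels are canonical and order-invariant", {
  x <- withr::with_seed(3, c(rnorm(60, 0.97, 0.02), rnorm(25, 0.8, 0.07)))
  f1 <- fit_mixture(x, k = 2, seed = 2)
  f2 <- fit_mixture(rev(x), k = 2, seed = 2)
  expect_true(f1$means[1] > f1$means[2])
  expect_equal(f1$means, f2$means, tolerance = 1e-4)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-4)
})

test_that("k=2 fit recovers known mixture parameters", {
  n <- 500
  x <- withr::with_seed(77, {
    comp <- rbinom(n, 1, 0.3)
    v <- ifelse(comp == 1, rnorm(n, 0.81, 0.08), rnorm(n, 0.97, 0.02))
    v[v > 1] <- 2 - v[v > 1]  # reflect the sliver above 1 back inside
    v
  })
  fit <- fit_mixture(x, k = 2, seed = 5)
  se_up <- 0.02 / sqrt(0.7 * n)
  se_lo <- 0.08 / sqrt(0.3 * n)
  expect_lt(abs(fit$means[1] - 0.97), 3 * se_up + 0.003)
  expect_lt(abs(fit$means[2] - 0.81), 3 * se_lo + 0.003)
  expect_lt(abs(fit$weights[2] - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 0.02)
})

test_that("bimodality verdict separates null and mixture cohorts", {
  # degenerate constant sample: blocked by the SD floor / separation rule
  const <- bimodality_verdict(rep(0.97, 30), seed = 1)
  expect_false(const$bimodal)

  # unimodal null: mostly not bimodal (full operating characteristics are
  # exercised in the acceptance suite)
  nulls <- vapply(1:40, function(s) {
    x <- withr::with_seed(s, rnorm(100, 0.97, 0.02))
    bimodality_verdict(x, seed = s)$bimodal
  }, NA)
  expect_gte(mean(!nulls), 0.9)

  # clearly bimodal screening cohorts
  bims <- vapply(1:10, function(s) {
    x <- withr::with_seed(s + 500,
                          c(rnorm(38, 0.97, 0.02), rnorm(12, 0.81, 0.08)))
    bimodality_verdict(x, seed = s)$bimodal
  }, NA)
  expect_true(all(bims))
})

test_that("mode assignment is posterior-based with a conservative tie", {
  fit <- structure(list(k = 2L, means = c(1.0, 0.8), sds = c(0.05, 0.05),
                        weights = c(0.5, 0.5), loglik = 0, bic = 0,
                        converged = TRUE, n_obs = 10, trace = 0),
                   class = "mixture_fit")
  # symmetric setup: posterior crossover is exactly at 0.9
  rep <- assign_and_report(c(0.9, 0.95, 0.85, NA), paste0("s", 1:4), fit,
                           bimodal = TRUE)
  a <- rep$assignments
  expect_identical(a$assigned_mode, c("lower", "upper", "lower", NA))
  expect_identical(a$screen_positive, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$lower_mode_proportion, 2 / 3)  # over defined ratios

  # not bimodal: everyone screens negative, proportion 0
  rep0 <- assign_and_report(c(0.99, 1.0, 0.98), paste0("s", 1:3), fit,
                            bimodal = FALSE)
  expect_equal(rep0$lower_mode_proportion, 0)
  expect_true(all(!rep0$assignments$screen_positive))
  expect_true(all(is.na(rep0$assignments$posterior_lower)))

  expect_error(assign_and_report(c(0.9, 0.8), "s1", fit), "equal length")
})

test_that("posterior_lower is zero under a single component", {
  f1 <- fit_mixture(withr::with_seed(2, rnorm(30, 0.95, 0.02)), k = 1)
  expect_identical(posterior_lower(f1, c(0.5, 0.9)), c(0, 0))
})

test_that("analyze_cohort ties the stages together", {
  pc <- mmr_preset("figure3")
  cc <- pc$cohort
  cc$seed <- 7L
  res <- process_cohort(cc, pc$blot, pc$stim)
  rep <- analyze_cohort(res$ratios, seed = 7)
  expect_true(rep$bimodal)
  expect_identical(nrow(rep$assignments), 50L)
  expect_equal(rep$fit$means[1], 0.97, tolerance = 0.03)
  expect_equal(rep$fit$means[2], 0.81, tolerance = 0.06)
  # screen positives are the low-ratio subjects
  a <- rep$assignments
  expect_true(max(a$ratio[a$screen_positive]) <
                min(a$ratio[!a$screen_positive]))
})
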