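#' Histogram of cohort ratios
#'
#' Right-closed bins `(lo, hi]` covering (0, 1]; counts over the defined
#' ratios sum to the number of defined ratios. Display only — never used for
#' inference.
#'
#' @param ratios ratios (any form accepted by the ratio accessors).
#' @param bin_width positive bin width (default 0.05).
#' @return data.frame: bin_lo, bin_hi, count. Empty input gives an empty
#'   table.
#' @export
ratio_histogram <- function(ratios, bin_width = 0.05) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  r <- as_ratio_vector(ratios)
  r <- r[is.finite(r)]
  if (!length(r))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  if (any(r <= 0 | r > 1))
    stop("ratios must lie in (0, 1]", call. = FALSE)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- tabulate(findInterval(r, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = counts)
}

# internal: log-likelihood matrix machinery for the EM fit
mix_loglik <- function(x, w, mu, sd) {
  lp <- vapply(seq_along(w), function(j)
    log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE),
    numeric(length(x)))
  m <- apply(lp, 1, max)
  list(loglik = sum(m + log(rowSums(exp(lp - m)))), lp = lp, m = m)
}

# internal: one EM run from a given start; loglik must be non-decreasing
em_run <- function(x, w, mu, sd, max_iter, tol, sd_floor) {
  n <- length(x)
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ml <- mix_loglik(x, w, mu, sd)
    ll <- ml$loglik
    if (ll < ll_prev - 1e-8 * (1 + abs(ll_prev)))
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    resp <- exp(ml$lp - ml$m)       # n x k, unnormalized
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
    sd <- pmax(sd, sd_floor)
  }
  list(w = w, mu = mu, sd = sd, loglik = trace[length(trace)],
       converged = converged, trace = trace)
}

#' Fit a Gaussian mixture to cohort ratios
#'
#' Maximum-likelihood fit on the raw ratio scale by
#' expectation-maximization with multiple starts (one quantile-based start
#' plus random restarts), keeping the best log-likelihood. An SD floor
#' prevents degenerate single-point spikes; truncation of the ratio scale at
#' 1 is ignored in the likelihood (the modes sit far enough from the
#' boundary that the effect is below the SD floor at the default presets).
#' Components are reported sorted by mean, descending: component 1 is the
#' upper mode.
#'
#' @param ratios ratios (any accepted form); needs at least `5 * k` defined
#'   values.
#' @param k number of components, 1 or 2.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of EM starts (default 10).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-8).
#' @param sd_floor lower bound for component SDs (default 1e-3).
#' @return an object of class `mixture_fit`: k, means, sds, weights,
#'   loglik, bic, converged, n_obs, and the best run's loglik `trace`.
#' @export
fit_mixture <- function(ratios, k = 2, seed = 1L, n_starts = 10,
                        max_iter = 500, tol = 1e-8, sd_floor = 1e-3) {
  x <- as_ratio_vector(ratios)
  x <- x[is.finite(x)]
  if (!k %in% c(1, 2)) stop("k must be 1 or 2", call. = FALSE)
  n <- length(x)
  if (n < 5 * k)
    stop(sprintf("too few observations: need >= %d defined ratios for k=%d",
                 5 * k, k), call. = FALSE)
  if (k == 1) {
    mu <- mean(x)
    sd1 <- max(sqrt(mean((x - mu)^2)), sd_floor)  # ML (n-denominator) SD
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    fit <- list(k = 1L, means = mu, sds = sd1, weights = 1,
                loglik = ll, bic = -2 * ll + 2 * log(n),
                converged = TRUE, n_obs = n, trace = ll)
    return(structure(fit, class = "mixture_fit"))
  }
  s_all <- max(stats::sd(x), sd_floor)
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      if (s == 1L) {
        mu0 <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
        sd0 <- rep(s_all, 2)
        w0 <- c(0.5, 0.5)
      } else {
        mu0 <- sample(x, 2)
        sd0 <- rep(s_all, 2) * stats::runif(2, 0.5, 1.5)
        w1 <- stats::runif(1, 0.2, 0.8)
        w0 <- c(w1, 1 - w1)
      }
      if (abs(mu0[1] - mu0[2]) < sd_floor)
        mu0 <- mu0 + c(-1, 1) * s_all / 2
      run <- em_run(x, w0, mu0, pmax(sd0, sd_floor), max_iter, tol,
                    sd_floor)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  ord <- order(best$mu, decreasing = TRUE)
  ll <- best$loglik
  structure(list(k = 2L, means = best$mu[ord], sds = best$sd[ord],
                 weights = best$w[ord], loglik = ll,
                 bic = -2 * ll + 5 * log(n),
                 converged = best$converged, n_obs = n,
                 trace = best$trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k=%d, n=%d, loglik %.3f, BIC %.3f%s\n",
              x$k, x$n_obs, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  for (j in seq_len(x$k))
    cat(sprintf("  comp %d: mean %.4f, sd %.4f, weight %.3f\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  invisible(x)
}

#' Posterior probability of the lower mode
#'
#' @param fit a k=2 [fit_mixture()] result.
#' @param ratios ratio values.
#' @return numeric vector of posterior probabilities for the lower-mean
#'   component (zeros for a k=1 fit).
#' @export
posterior_lower <- function(fit, ratios) {
  stopifnot(inherits(fit, "mixture_fit"))
  x <- as_ratio_vector(ratios)
  if (fit$k == 1L) return(rep(0, length(x)))
  d1 <- fit$weights[1] * stats::dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(x, fit$means[2], fit$sds[2])
  out <- d2 / (d1 + d2)
  out[!is.finite(x)] <- NA_real_
  out
}

#' Bimodality verdict for a cohort ratio distribution
#'
#' Fits k=1 and k=2 mixtures and calls the distribution bimodal when the
#' two-component model is decisively preferred, `BIC(2) < BIC(1) - 2`, and
#' the fitted means are separated by more than
#' `max(tol_sep, sep_mult * 2 * sd1)` where `sd1` is the SD of the dominant
#' upper-mode component (see the methods vignette for why the separation is
#' judged against the sharper major mode rather than the wider minor one).
#'
#' @param ratios ratios (any accepted form).
#' @param seed integer seed passed to the mixture fits.
#' @param bic_margin required BIC advantage of k=2 (default 2).
#' @param tol_sep absolute minimum mean separation (default 0.02).
#' @param sep_mult multiplier on `2 * sd1` (default 1).
#' @return an object of class `bimodality_verdict`: list with `bimodal`
#'   (logical) and `evidence` (both fits, the BIC difference, separation and
#'   its threshold).
#' @export
bimodality_verdict <- function(ratios, seed = 1L, bic_margin = 2,
                               tol_sep = 0.02, sep_mult = 1) {
  fit1 <- fit_mixture(ratios, k = 1, seed = seed)
  fit2 <- fit_mixture(ratios, k = 2, seed = seed)
  sep <- fit2$means[1] - fit2$means[2]
  thr <- max(tol_sep, sep_mult * 2 * fit2$sds[1])
  bimodal <- (fit2$bic < fit1$bic - bic_margin) && (sep > thr)
  structure(list(bimodal = bimodal,
                 evidence = list(fit_k1 = fit1, fit_k2 = fit2,
                                 bic_diff = fit1$bic - fit2$bic,
                                 separation = sep,
                                 sep_threshold = thr)),
            class = "bimodality_verdict")
}

#' @export
print.bimodality_verdict <- function(x, ...) {
  e <- x$evidence
  cat(sprintf(
    "<bimodality_verdict> %s (BIC diff %.2f, separation %.3f vs %.3f)\n",
    if (x$bimodal) "bimodal" else "not bimodal",
    e$bic_diff, e$separation, e$sep_threshold))
  invisible(x)
}

#' Mode assignment and cohort screening report
#'
#' Assigns each subject to the mixture component with the higher posterior;
#' a subject exactly at the posterior crossover is assigned to the lower
#' mode (conservative tie-break: screening positives proceed to genetic
#' testing). Subjects assigned to the lower mode are screen positive. When
#' the cohort is not bimodal, no assignment is meaningful: all subjects are
#' screen negative, posteriors are reported as NA, and the lower-mode
#' proportion is 0.
#'
#' @param ratios ratio values.
#' @param subject_ids identifiers, same length as `ratios`.
#' @param fit a k=2 [fit_mixture()] result.
#' @param bimodal logical verdict (see [bimodality_verdict()]).
#' @return an object of class `cohort_report`: list with `fit`, `bimodal`,
#'   `lower_mode_proportion`, and `assignments` (data.frame: subject_id,
#'   ratio, posterior_lower, assigned_mode, screen_positive).
#' @export
assign_and_report <- function(ratios, subject_ids, fit, bimodal = TRUE) {
  x <- as_ratio_vector(ratios)
  if (length(x) != length(subject_ids))
    stop("ratios and subject_ids must have equal length", call. = FALSE)
  defined <- is.finite(x)
  if (isTRUE(bimodal) && fit$k == 2L) {
    post <- posterior_lower(fit, x)
    assigned <- ifelse(defined, ifelse(post >= 0.5, "lower", "upper"),
                       NA_character_)
    screen <- !is.na(assigned) & assigned == "lower"
    prop <- if (any(defined)) mean(assigned[defined] == "lower") else 0
  } else {
    post <- rep(NA_real_, length(x))
    assigned <- ifelse(defined, "upper", NA_character_)
    screen <- rep(FALSE, length(x))
    prop <- 0
  }
  structure(list(fit = fit, bimodal = isTRUE(bimodal),
                 lower_mode_proportion = prop,
                 assignments = data.frame(
                   subject_id = as.character(subject_ids), ratio = x,
                   posterior_lower = post, assigned_mode = assigned,
                   screen_positive = screen, stringsAsFactors = FALSE)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %s; lower-mode proportion %.3f (%d of %d subjects)\n",
    if (x$bimodal) "bimodal" else "not bimodal",
    x$lower_mode_proportion, sum(x$assignments$screen_positive),
    nrow(x$assignments)))
  invisible(x)
}

#' One-call cohort analysis
#'
#' Runs [bimodality_verdict()] and [assign_and_report()] on a vector of
#' cohort ratios.
#'
#' @param ratios ratios; a data.frame with `sample_id` supplies ids.
#' @param subject_ids identifiers (default: taken from the data.frame or
#'   generated).
#' @param seed integer seed for the mixture fits.
#' @param ... passed to [bimodality_verdict()].
#' @return a `cohort_report` with the verdict attached as `$verdict`.
#' @export
analyze_cohort <- function(ratios, subject_ids = NULL, seed = 1L, ...) {
  if (is.null(subject_ids)) {
    subject_ids <- if (is.data.frame(ratios) && "sample_id" %in%
                         names(ratios)) ratios$sample_id
    else sprintf("S%03d", seq_along(as_ratio_vector(ratios)))
  }
  verdict <- bimodality_verdict(ratios, seed = seed, ...)
  report <- assign_and_report(ratios, subject_ids,
                              verdict$evidence$fit_k2, verdict$bimodal)
  report$verdict <- verdict
  report
}

#' Plot a cohort ratio distribution
#'
#' Histogram of the ratios with the fitted mixture components overlaid
#' (base graphics).
#'
#' @param x a `cohort_report`.
#' @param bin_width histogram bin width.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cohort_report <- function(x, bin_width = 0.05, ...) {
  r <- x$assignments$ratio
  r <- r[is.finite(r)]
  h <- graphics::hist(r, breaks = seq(0, 1, by = bin_width), right = TRUE,
                      freq = FALSE, xlab = "MMR ratio",
                      main = "Cohort MMR ratio distribution", ...)
  fit <- x$fit
  xs <- seq(0, 1, length.out = 400)
  for (j in seq_len(fit$k))
    graphics::lines(xs, fit$weights[j] *
                      stats::dnorm(xs, fit$means[j], fit$sds[j]),
                    lty = j, lwd = 2)
  invisible(h)
}
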