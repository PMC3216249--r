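#' @keywords internal
"_PACKAGE"

#' Derive a deterministic child seed
#'
#' Stochastic stages and per-subject draws each get their own RNG stream so
#' that, e.g., adding subjects to a cohort never reshuffles earlier ones.
#' The child seed is a stable integer hash of the master seed and a key
#' string, kept strictly below 2^31.
#'
#' @param seed master seed (integer).
#' @param key character scalar naming the stream (e.g. `"subject-7"`).
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483629  # large prime < 2^31; products stay exact in doubles
  h <- abs(as.numeric(seed)) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

# internal: draw from a normal truncated to [lo, hi] by inverse CDF.
# sd = 0 degenerates to the clamped mean (used by carrier_ratio_sd = 0).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi <= p_lo) return(rep(min(max(mean, lo), hi), n))
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# internal argument checkers
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  ok <- (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stop(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
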