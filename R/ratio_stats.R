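#' The MMR ratio statistic
#'
#' Ratio of the two background-subtracted band densities with the smaller
#' value always in the numerator and the larger in the denominator, so the
#' ratio lies in (0, 1]: the further below 1.0, the greater the deficit of
#' the lower protein relative to the other. The ratio is undefined (NA)
#' whenever either net density is non-positive, non-finite, or flagged
#' non-detectable; such results carry a `"nondetectable_band"` QC flag and
#' are excluded from downstream summaries rather than imputed.
#'
#' @param mlh1_net,msh2_net net band densities.
#' @param mlh1_detectable,msh2_detectable detectability calls from the
#'   densitometry stage.
#' @param sample_id optional identifier.
#' @return an object of class `ratio_result`: list with `sample_id`,
#'   `ratio` (NA when undefined), `lower_protein` (`"MLH1"`, `"MSH2"`,
#'   `"tie"` or `"undefined"`), `mlh1_net`, `msh2_net`, `qc_flags`.
#' @export
mmr_ratio <- function(mlh1_net, msh2_net,
                      mlh1_detectable = TRUE, msh2_detectable = TRUE,
                      sample_id = NA_character_) {
  qc <- character(0)
  ok <- is.finite(mlh1_net) && is.finite(msh2_net) &&
    mlh1_net > 0 && msh2_net > 0 &&
    isTRUE(mlh1_detectable) && isTRUE(msh2_detectable)
  if (!ok) {
    qc <- "nondetectable_band"
    res <- list(sample_id = sample_id, ratio = NA_real_,
                lower_protein = "undefined",
                mlh1_net = mlh1_net, msh2_net = msh2_net, qc_flags = qc)
    return(structure(res, class = "ratio_result"))
  }
  ratio <- min(mlh1_net, msh2_net) / max(mlh1_net, msh2_net)
  lower <- if (mlh1_net < msh2_net) "MLH1"
           else if (msh2_net < mlh1_net) "MSH2" else "tie"
  structure(list(sample_id = sample_id, ratio = ratio,
                 lower_protein = lower, mlh1_net = mlh1_net,
                 msh2_net = msh2_net, qc_flags = qc),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %s: ratio %s, lower %s\n",
              x$sample_id,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              x$lower_protein))
  invisible(x)
}

#' MMR ratios for a band-measurement table
#'
#' Pivots a tidy densitometry table (one row per sample x protein, as
#' produced by [quantify_sample()]) into one [mmr_ratio()] result per
#' sample.
#'
#' @param measurements data.frame with columns `sample_id`, `protein`,
#'   `net`, `detectable`.
#' @return data.frame: sample_id, ratio, lower_protein, mlh1_net, msh2_net,
#'   qc_flags (`";"`-separated).
#' @export
mmr_ratios <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("sample_id", "protein", "net", "detectable") %in%
                  names(measurements)))
  ids <- unique(measurements$sample_id)
  rows <- lapply(ids, function(id) {
    m <- measurements[measurements$sample_id == id, , drop = FALSE]
    pick <- function(p, col) {
      v <- m[[col]][m$protein == p]
      if (length(v) != 1L)
        stop(sprintf("sample '%s' needs exactly one %s row", id, p),
             call. = FALSE)
      v
    }
    r <- mmr_ratio(pick("MLH1", "net"), pick("MSH2", "net"),
                   pick("MLH1", "detectable"), pick("MSH2", "detectable"),
                   sample_id = id)
    data.frame(sample_id = id, ratio = r$ratio,
               lower_protein = r$lower_protein,
               mlh1_net = r$mlh1_net, msh2_net = r$msh2_net,
               qc_flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: coerce various ratio containers to a numeric vector
as_ratio_vector <- function(x) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "ratio_result")) return(x$ratio)
  if (is.data.frame(x) && "ratio" %in% names(x)) return(x$ratio)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "ratio_result")))
    return(vapply(x, function(r) r$ratio, 0))
  stop("cannot interpret input as ratios", call. = FALSE)
}

#' Replicate reproducibility summary
#'
#' Mean and replicate standard deviation (SDE; sample SD with n-1
#' denominator) over the defined ratios of one sample. Undefined ratios are
#' dropped and do not count towards `n_reps`.
#'
#' @param ratios numeric vector of ratios, a data.frame with a `ratio`
#'   column, or a list of [mmr_ratio()] results.
#' @param sample_id optional identifier.
#' @return one-row data.frame: sample_id, n_reps, mean_ratio, sde_ratio.
#' @export
summarize_replicates <- function(ratios, sample_id = NA_character_) {
  r <- as_ratio_vector(ratios)
  if (is.data.frame(ratios) && "sample_id" %in% names(ratios) &&
      is.na(sample_id) && length(unique(ratios$sample_id)) == 1L)
    sample_id <- ratios$sample_id[1]
  r <- r[is.finite(r)]
  if (length(r) < 2L)
    stop("insufficient replicates: need >= 2 defined ratios",
         call. = FALSE)
  data.frame(sample_id = sample_id, n_reps = length(r),
             mean_ratio = mean(r), sde_ratio = stats::sd(r),
             stringsAsFactors = FALSE)
}

#' Pool replicate ratios across samples
#'
#' Overall mean and SDE over the concatenated defined ratios of all listed
#' samples (not a mean of per-sample means).
#'
#' @param ratio_sets a list of ratio vectors (one element per sample), a
#'   single numeric vector, or a data.frame with a `ratio` column.
#' @return one-row data.frame: n, mean_ratio, sde_ratio.
#' @export
pool_overall <- function(ratio_sets) {
  if (is.data.frame(ratio_sets) || is.numeric(ratio_sets))
    ratio_sets <- list(ratio_sets)
  if (!length(ratio_sets)) stop("no ratio sets to pool", call. = FALSE)
  r <- unlist(lapply(ratio_sets, as_ratio_vector), use.names = FALSE)
  r <- r[is.finite(r)]
  if (!length(r)) stop("no defined ratios to pool", call. = FALSE)
  data.frame(n = length(r), mean_ratio = mean(r),
             sde_ratio = if (length(r) >= 2L) stats::sd(r) else NA_real_)
}
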