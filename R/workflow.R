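#' Pipeline run configuration
#'
#' @param out_dir output directory for the run.
#' @param preset cohort preset name (see [mmr_preset()]).
#' @param seed master seed; every stochastic stage receives a deterministic
#'   child seed derived from it and the stage name.
#' @param stages character subset of
#'   `c("simulate", "quantify", "ratio", "cohort")`; stages always execute
#'   in that canonical order.
#' @param write_image write the simulated blot as a 16-bit TIFF (default
#'   TRUE; required if `quantify` is run in a later partial run).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, preset = "figure3", seed = 1L,
                       stages = c("simulate", "quantify", "ratio",
                                  "cohort"),
                       write_image = TRUE,
                       log_level = c("info", "quiet")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, preset = preset,
                 seed = as.integer(seed), stages = stages,
                 write_image = isTRUE(write_image),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Simulate, quantify and score a cohort in memory
#'
#' Convenience wrapper for the full simulate -> quantify -> ratio chain on a
#' cohort preset or explicit configs; used by the pipeline runner and by
#' simulation studies.
#'
#' @param cohort a [cohort_config()] or `mmr_cohort`.
#' @param blot a [blot_config()].
#' @param stim a [stimulation_params()].
#' @param image_seed seed for the blot noise.
#' @param lod_abs,lod_snr detectability thresholds.
#' @return list with `cohort`, `image`, `measurements`, `ratios` (the ratio
#'   table joined with the generating truth).
#' @export
process_cohort <- function(cohort, blot = blot_config(),
                           stim = stimulation_params(),
                           image_seed = NULL, lod_abs = 300, lod_snr = 3) {
  if (inherits(cohort, "cohort_config")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "mmr_cohort"))
  image_seed <- image_seed %||% child_seed(cohort$config$seed, "image")
  image <- simulate_blot_image(cohort$subjects, blot, stim,
                               seed = image_seed)
  meas <- quantify_sample(image, lod_abs = lod_abs, lod_snr = lod_snr)
  ratios <- mmr_ratios(meas)
  ratios <- merge(ratios, cohort$truth, by.x = "sample_id",
                  by.y = "subject_id", sort = FALSE)
  list(cohort = cohort, image = image, measurements = meas,
       ratios = ratios)
}

# internal: stage logger
pipeline_logger <- function(config) {
  log_path <- file.path(config$out_dir, "run.log")
  function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    if (config$log_level != "quiet") message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order (simulate -> quantify -> ratio ->
#' cohort) into a run directory and writes a machine-readable manifest
#' recording the configuration hash, per-stage child seeds, package
#' version, and MD5 checksums of every output file. A disabled stage whose
#' output is needed downstream must have been produced by a previous run
#' into the same directory; otherwise the run fails naming the missing
#' stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `out_dir`, `manifest`, and the in-memory
#'   stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_logger(config)
  preset <- mmr_preset(config$preset)
  if (preset$kind != "cohort")
    stop("run_pipeline drives cohort presets; got kind '", preset$kind,
         "'", call. = FALSE)
  seeds <- list(simulate = child_seed(config$seed, "simulate"),
                image = child_seed(config$seed, "image"),
                cohort = child_seed(config$seed, "cohort"))
  path <- function(f) file.path(config$out_dir, f)
  state <- list()
  need <- function(file, stage, upstream) {
    if (!file.exists(path(file)))
      stop(sprintf("stage '%s': missing upstream output '%s' (run '%s')",
                   stage, file, upstream), call. = FALSE)
    path(file)
  }

  if ("simulate" %in% config$stages) {
    log("simulate: preset '%s', seed %d", config$preset, seeds$simulate)
    cc <- preset$cohort
    cc$seed <- seeds$simulate
    state$cohort <- simulate_cohort(cc)
    state$image <- simulate_blot_image(state$cohort$subjects, preset$blot,
                                       preset$stim, seed = seeds$image)
    utils::write.csv(state$cohort$truth, path("ground_truth.csv"),
                     row.names = FALSE)
    if (config$write_image)
      write_blot_tiff(state$image, path("blot.tif"))
    log("simulate: %d subjects, image %d x %d px",
        nrow(state$cohort$truth), nrow(state$image$pixels),
        ncol(state$image$pixels))
  }

  if ("quantify" %in% config$stages) {
    if (is.null(state$image)) {
      state$image <- read_blot_tiff(need("blot.tif", "quantify",
                                         "simulate"))
    }
    state$measurements <- quantify_sample(state$image,
                                          lod_abs = preset$lod_abs,
                                          lod_snr = preset$lod_snr)
    utils::write.csv(state$measurements, path("band_measurements.csv"),
                     row.names = FALSE)
    log("quantify: %d band measurements, %d detectable",
        nrow(state$measurements), sum(state$measurements$detectable))
  }

  if ("ratio" %in% config$stages) {
    if (is.null(state$measurements))
      state$measurements <- utils::read.csv(
        need("band_measurements.csv", "ratio", "quantify"))
    state$ratios <- mmr_ratios(state$measurements)
    utils::write.csv(state$ratios, path("ratios.csv"), row.names = FALSE)
    log("ratio: %d samples, %d defined ratios", nrow(state$ratios),
        sum(is.finite(state$ratios$ratio)))
  }

  if ("cohort" %in% config$stages) {
    if (is.null(state$ratios))
      state$ratios <- utils::read.csv(need("ratios.csv", "cohort",
                                           "ratio"))
    state$report <- analyze_cohort(state$ratios, seed = seeds$cohort)
    utils::write.csv(state$report$assignments, path("assignments.csv"),
                     row.names = FALSE)
    fit <- state$report$fit
    ev <- state$report$verdict$evidence
    jsonlite::write_json(
      list(bimodal = state$report$bimodal,
           lower_mode_proportion = state$report$lower_mode_proportion,
           fit = list(k = fit$k, means = fit$means, sds = fit$sds,
                      weights = fit$weights, loglik = fit$loglik,
                      bic = fit$bic, converged = fit$converged,
                      n_obs = fit$n_obs),
           evidence = list(bic_k1 = ev$fit_k1$bic, bic_k2 = ev$fit_k2$bic,
                           bic_diff = ev$bic_diff,
                           separation = ev$separation,
                           sep_threshold = ev$sep_threshold)),
      path("cohort_report.json"), auto_unbox = TRUE, digits = NA)
    log("cohort: %s, lower-mode proportion %.3f",
        if (state$report$bimodal) "bimodal" else "not bimodal",
        state$report$lower_mode_proportion)
  }

  cfg_path <- path("config.json")
  write_run_config(config, cfg_path)
  outputs <- intersect(c("ground_truth.csv", "blot.tif", "blot.tif.json",
                         "band_measurements.csv", "ratios.csv",
                         "assignments.csv", "cohort_report.json"),
                       list.files(config$out_dir))
  checksums <- tools::md5sum(vapply(outputs, path, ""))
  names(checksums) <- outputs
  manifest <- list(package = "mmrblot",
                   version = as.character(utils::packageVersion("mmrblot")),
                   preset = config$preset, master_seed = config$seed,
                   stage_seeds = seeds,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   checksums = as.list(checksums))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log("done: %s", config$out_dir)
  invisible(c(list(out_dir = config$out_dir, manifest = manifest), state))
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher used by the `inst/cli/mmrblot` script:
#' `simulate-cohort`, `simulate-blot`, `quantify`, `ratio`, `cohort`,
#' `run-all`. Options are `--key value` pairs.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mmrblot <subcommand> [--key value ...]",
    "  simulate-cohort --out DIR [--preset NAME] [--seed N]",
    "  simulate-blot   --out DIR [--preset NAME] [--seed N]",
    "  quantify        --image FILE.tif | --profiles FILE.csv --config FILE.json",
    "                  --out DIR [--manifest FILE.csv] [--lod-abs X] [--lod-snr X]",
    "  ratio           --measurements FILE.csv --out DIR",
    "  cohort          --ratios FILE.csv --out DIR [--seed N]",
    "  run-all         --out DIR [--preset NAME] [--seed N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  kv <- args[-1]
  if (length(kv) %% 2 != 0 || (length(kv) && !all(grepl("^--", kv[c(TRUE,
                                                                    FALSE)])))) {
    message(usage); return(invisible(1L))
  }
  opt <- stats::setNames(as.list(kv[c(FALSE, TRUE)]),
                         sub("^--", "", kv[c(TRUE, FALSE)]))
  get <- function(name, default = NULL) opt[[name]] %||% default
  req <- function(name) get(name) %||%
    stop(sprintf("missing required option --%s", name), call. = FALSE)
  status <- tryCatch({
    switch(cmd,
           `run-all` = ,
           `simulate-cohort` = ,
           `simulate-blot` = {
             stages <- if (cmd == "run-all")
               c("simulate", "quantify", "ratio", "cohort") else "simulate"
             run_pipeline(run_config(req("out"),
                                     preset = get("preset", "figure3"),
                                     seed = as.integer(get("seed", "1")),
                                     stages = stages))
             0L
           },
           quantify = {
             x <- if (!is.null(get("profiles")))
               read_profiles_csv(get("profiles"))
             else read_blot_tiff(req("image"))
             blot <- if (!is.null(get("config"))) do.call(
               blot_config, jsonlite::read_json(get("config"),
                                                simplifyVector = TRUE))
             manifest <- if (!is.null(get("manifest")))
               utils::read.csv(get("manifest"), stringsAsFactors = FALSE)
             out <- req("out")
             dir.create(out, recursive = TRUE, showWarnings = FALSE)
             m <- quantify_sample(
               x, manifest = manifest, blot = blot,
               lod_abs = as.numeric(get("lod-abs", "300")),
               lod_snr = as.numeric(get("lod-snr", "3")))
             utils::write.csv(m, file.path(out, "band_measurements.csv"),
                              row.names = FALSE)
             0L
           },
           ratio = {
             m <- utils::read.csv(req("measurements"))
             out <- req("out")
             dir.create(out, recursive = TRUE, showWarnings = FALSE)
             utils::write.csv(mmr_ratios(m), file.path(out, "ratios.csv"),
                              row.names = FALSE)
             0L
           },
           cohort = {
             r <- utils::read.csv(req("ratios"))
             out <- req("out")
             dir.create(out, recursive = TRUE, showWarnings = FALSE)
             rep <- analyze_cohort(r, seed = as.integer(get("seed", "1")))
             utils::write.csv(rep$assignments,
                              file.path(out, "assignments.csv"),
                              row.names = FALSE)
             jsonlite::write_json(
               list(bimodal = rep$bimodal,
                    lower_mode_proportion = rep$lower_mode_proportion,
                    means = rep$fit$means, sds = rep$fit$sds,
                    weights = rep$fit$weights),
               file.path(out, "cohort_report.json"), auto_unbox = TRUE,
               digits = NA)
             0L
           },
           { message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
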