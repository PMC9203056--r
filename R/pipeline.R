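#' Default pipeline configuration
#'
#' Returns the full pipeline configuration as a nested list; every numeric
#' default equals the documented analysis value (20-250 Hz order-2 bandpass,
#' 500 Hz, epochs -0.2 to 1.6 s, 100 uV baseline rejection, +/-5-sample RMS,
#' z threshold 1.2, 8 ms onset run, staircase 250/50/100-800, 10,000
#' split-half permutations). A YAML copy ships in
#' `system.file("extdata", "default-config.yml", package = "premg")`.
#'
#' @param path optional YAML file to load instead of the defaults; values
#'   present in the file override the defaults section-wise.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(path = NULL) {
  cfg <- list(
    seed = 1,
    sim = unclass(simConfig()),
    emg = unclass(emgConfig()),
    preprocess = unclass(preprocessConfig()),
    detect = unclass(detectionConfig()),
    reliability = list(n_perm = 10000, titration_reps = 1000,
                       titration_min = 6, method = "pearson"),
    inputs = list(recordings = NULL, trials = NULL, format = "brainvision"),
    events = list(go = "go", stop = "stop"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (is.list(user[[sec]]) && sec %in% names(cfg))
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      else cfg[[sec]] <- user[[sec]]
    }
  }
  cfg$sim$seed <- cfg$seed
  cfg
}

.cfgPreprocess <- function(cfg) {
  p <- cfg$preprocess
  preprocessConfig(band = unlist(p$band), filter_order = p$filter_order,
                   target_rate = p$target_rate,
                   epoch_window = unlist(p$epoch_window),
                   baseline_window = unlist(p$baseline_window),
                   reject_baseline_uV = p$reject_baseline_uV,
                   rms_halfwidth = p$rms_halfwidth,
                   zero_phase = isTRUE(p$zero_phase))
}

.cfgDetect <- function(cfg) {
  d <- cfg$detect
  detectionConfig(threshold = d$threshold, onset_run_ms = d$onset_run_ms,
                  search_window = unlist(d$search_window))
}

.cfgSim <- function(cfg) do.call(simConfig, cfg$sim)

.cfgEmg <- function(cfg) do.call(emgConfig, cfg$emg)

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (or reading the
#' configured input files), `preprocess`, `detect`, `metrics`,
#' `reliability` — writing tidy per-trial and per-participant CSVs plus a
#' machine-readable JSON report (parameters, seed, rejection counts, summary
#' metrics) under `out_dir`. All randomness is seeded from the config.
#'
#' @param config a [pipelineConfig()] list or a YAML path.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "detect", "metrics", "reliability")`.
#' @param out_dir output directory.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "preprocess", "detect",
                                   "metrics", "reliability"),
                        out_dir = "premg-out") {
  if (is.character(config)) config <- pipelineConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "premg",
                 version = as.character(utils::packageVersion("premg")),
                 seed = config$seed, stages = stages,
                 parameters = config[c("sim", "emg", "preprocess",
                                       "detect", "reliability")])
  pre_cfg <- .cfgPreprocess(config)
  det_cfg <- .cfgDetect(config)

  if ("simulate" %in% stages) {
    sim <- simulateCohort(.cfgSim(config), .cfgEmg(config))
    trials <- sim$trials
    recordings <- sim$recordings
    writeTrialTable(trials, file.path(out_dir, "trials.tsv"))
    utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, na = "")
  } else {
    if (is.null(config$inputs$trials))
      stop("no trial table configured for stage 'preprocess'",
           call. = FALSE)
    if (!file.exists(config$inputs$trials))
      stop(sprintf("trial table not found: %s", config$inputs$trials),
           call. = FALSE)
    trials <- readTrialTable(config$inputs$trials)
    if (!"participant" %in% names(trials)) trials$participant <- 1L
    paths <- config$inputs$recordings
    for (pth in paths)
      if (!file.exists(pth))
        stop(sprintf("recording not found: %s", pth), call. = FALSE)
    recordings <- lapply(paths, readContinuousRecording,
                         format = config$inputs$format)
  }

  if (!any(c("preprocess", "detect", "metrics", "reliability") %in% stages)) {
    writeReport(report, file.path(out_dir, "report.json"))
    return(invisible(report))
  }

  ids <- sort(unique(trials$participant))
  bursts_all <- vector("list", length(ids))
  summaries <- vector("list", length(ids))
  rejections <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- trials[trials$participant == ids[k], ]
    epochs <- preprocessEmg(recordings[[k]], tr, pre_cfg)
    rej <- rejectedReasons(epochs)
    rejections[[k]] <- data.frame(participant = ids[k],
                                  n_trials = length(rej),
                                  n_rejected = sum(!is.na(rej)))
    if (any(c("detect", "metrics", "reliability") %in% stages)) {
      b <- extractBursts(epochs, det_cfg)
      b <- cbind(participant = ids[k], b)
      bursts_all[[k]] <- b
      if ("metrics" %in% stages)
        summaries[[k]] <- cbind(participant = ids[k],
                                participantSummary(tr, b, epochs))
    }
  }
  report$rejections <- do.call(rbind, rejections)

  if (any(c("detect", "metrics", "reliability") %in% stages)) {
    bursts <- do.call(rbind, bursts_all)
    writeBurstTable(bursts, file.path(out_dir, "bursts.csv"))
  }

  if ("metrics" %in% stages) {
    summary_df <- do.call(rbind, summaries)
    writeSummary(summary_df, file.path(out_dir, "participants.csv"))
    inh <- inhibitionFunctions(bursts, config$sim$staircase_step)
    utils::write.csv(inh$group,
                     file.path(out_dir, "inhibition_functions.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(ssdProfiles(bursts, config$sim$staircase_step),
                     file.path(out_dir, "ssd_profiles.csv"),
                     row.names = FALSE, na = "")
    st <- tryCatch(singleTrialPrepare(bursts), error = function(e) NULL)
    if (!is.null(st))
      utils::write.csv(st, file.path(out_dir, "single_trial.csv"),
                       row.names = FALSE, na = "")
    vb <- peakLatencyVariability(bursts)
    utils::write.csv(vb, file.path(out_dir, "variability.csv"),
                     row.names = FALSE, na = "")
    report$metrics <- list(
      mean_ssrt = mean(summary_df$ssrt, na.rm = TRUE),
      mean_stop_accuracy_pct = mean(summary_df$stop_accuracy_pct),
      mean_ssd = mean(summary_df$mean_ssd),
      premg_frequency_pct = mean(summary_df$sstop_pct, na.rm = TRUE),
      premg_peak_latency = mean(summary_df$premg_peak_single,
                                na.rm = TRUE),
      ustop_peak_latency = mean(summary_df$ustop_peak_stop, na.rm = TRUE),
      mean_motor_time = mean(summary_df$go_motor_time, na.rm = TRUE),
      mean_premg_sd = mean(vb$sd_peak[!vb$outlier], na.rm = TRUE))
  }

  if ("reliability" %in% stages) {
    pr <- bursts[bursts$emg_class == "premg", ]
    rel_cfg <- config$reliability
    rel <- lapply(c(onset = "onset_go", peak = "peak_stop",
                    amplitude = "peak_amp", auc = "auc"), function(col)
      tryCatch(splitHalf(pr[[col]], pr$participant,
                         n_perm = rel_cfg$n_perm,
                         seed = config$seed,
                         method = rel_cfg$method, metric = col),
               error = function(e) NULL))
    rel <- rel[!vapply(rel, is.null, logical(1))]
    if (length(rel)) {
      rel_df <- do.call(rbind, lapply(rel, function(r)
        data.frame(metric = r$metric, r_mean = r$r_mean, r_sd = r$r_sd,
                   ci_low = r$ci[1], ci_high = r$ci[2],
                   n_perm = r$n_perm, n_trials = r$n_trials_used,
                   n_participants = r$n_participants)))
      utils::write.csv(rel_df, file.path(out_dir, "reliability.csv"),
                       row.names = FALSE, na = "")
      report$reliability <- rel_df
    }
    tit <- tryCatch(
      titration(pr$peak_stop, pr$participant,
                k_min = rel_cfg$titration_min,
                n_reps = rel_cfg$titration_reps, seed = config$seed,
                method = rel_cfg$method),
      error = function(e) NULL)
    if (!is.null(tit))
      utils::write.csv(tit, file.path(out_dir, "titration.csv"),
                       row.names = FALSE, na = "")
  }

  writeReport(report, file.path(out_dir, "report.json"))
  invisible(report)
}
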