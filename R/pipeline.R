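#' Pipeline configuration
#'
#' Builds a validated configuration for the command-level entry points from
#' a YAML file or a nested list. Unknown keys are rejected; missing keys
#' take the package defaults shown below.
#'
#' @param x path to a YAML file, or a nested list, or `NULL` for the
#'   defaults.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- list(
    video = list(path = NULL, mode = "RGB", fps = 30, roi = NULL),
    ecg = list(path = NULL, fs = 2000),
    evm = list(alpha = 50, levels = 4, band_bpm = c(90, 200)),
    wavelet = list(step_bpm = 0.5),
    select = list(criterion = "band_power", fraction = 0.1),
    pass2 = list(margin_bpm = 10, adaptive = TRUE),
    smooth = list(window_s = 20),
    coherence = list(grid = c(10, 10), freq_range = c(0.02, 0.5),
                     order = "max_then_mean"),
    events = list(path = NULL, window = c(-16, 16), baseline = c(-13, -3),
                  pre = c(-13, -3), post = c(3, 13)),
    out_dir = ".",
    seed = 1
  )
  user <- if (is.null(x)) list()
    else if (is.character(x)) yaml::read_yaml(x)
    else if (is.list(x)) x
    else stop("config must be a YAML path or a list", call. = FALSE)
  cfg <- merge_config(defaults, user, path = "")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(def, usr, path) {
  extra <- setdiff(names(usr), names(def))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "),
         call. = FALSE)
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]], as.list(usr[[k]]),
                               paste0(path, ".", k))
    } else {
      def[[k]] <- usr[[k]]
    }
  }
  def
}

cfg_params <- function(cfg, fps) {
  evm_params(alpha = cfg$evm$alpha, band_bpm = cfg$evm$band_bpm,
             levels = cfg$evm$levels, fps = fps)
}

cfg_estimate <- function(cfg, clip, roi = NULL) {
  estimate_hr(clip, roi = roi,
              params = cfg_params(cfg, clip$fps_nominal),
              select_criterion = cfg$select$criterion,
              select_fraction = cfg$select$fraction,
              step_bpm = cfg$wavelet$step_bpm,
              margin_bpm = cfg$pass2$margin_bpm,
              adaptive_margin = isTRUE(cfg$pass2$adaptive),
              window_s = cfg$smooth$window_s)
}

hr_to_df <- function(hr) {
  data.frame(time_s = hr$times, bpm = hr$bpm,
             valid = as.integer(hr$edge_mask))
}

write_hr_csv <- function(hr, path) {
  utils::write.csv(hr_to_df(hr), path, row.names = FALSE)
  invisible(path)
}

#' Read a heart-rate series written by the pipeline
#'
#' @param path CSV with columns `time_s,bpm,valid`.
#' @param source series provenance label.
#' @return an [hr_series].
#' @export
read_hr_csv <- function(path, source = "EVM") {
  df <- utils::read.csv(path)
  hr_series(df$time_s, df$bpm, source = source,
            smoothed = TRUE, edge_mask = df$valid > 0)
}

#' Run the heart-rate estimation pipeline
#'
#' Loads (or accepts) a video, runs the two-pass estimator and writes
#' `hr.csv` (`time_s,bpm,valid`) plus a machine-readable `estimate.json`
#' report carrying the pass-1 approximation, the refined band and the
#' effective parameters.
#'
#' @param config a [pipeline_config] (or anything it accepts).
#' @param clip optional in-memory [video_clip]; otherwise loaded from
#'   `config$video$path`.
#' @return the [estimate_hr()] fit, invisibly; files under
#'   `config$out_dir`.
#' @export
run_estimate <- function(config = NULL, clip = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(clip)) {
    if (is.null(cfg$video$path))
      stop("no video path in config and no clip supplied", call. = FALSE)
    clip <- load_video(cfg$video$path, mode = cfg$video$mode,
                       fps = cfg$video$fps)
  }
  r <- if (!is.null(cfg$video$roi)) do.call(roi, as.list(cfg$video$roi))
  message(sprintf("[estimate] alpha=%g levels=%d band=[%g,%g] BPM select=%s/%.2g",
                  cfg$evm$alpha, cfg$evm$levels, cfg$evm$band_bpm[1],
                  cfg$evm$band_bpm[2], cfg$select$criterion,
                  cfg$select$fraction))
  fit <- cfg_estimate(cfg, clip, roi = r)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hr_csv(fit$hr, file.path(cfg$out_dir, "hr.csv"))
  rep <- list(hr_approx_pass1 = fit$pass1$hr_approx,
              band_pass1 = fit$pass1$band, band_pass2 = fit$band2,
              margin_used = fit$pass1$margin_used,
              n_samples = length(fit$hr$times),
              n_valid = sum(fit$hr$edge_mask),
              median_bpm = stats::median(fit$hr$bpm[fit$hr$edge_mask]),
              # analysis parameters only: I/O paths are not part of the
              # scientific configuration a run is reproduced from
              config = unclass(cfg)[c("evm", "wavelet", "select", "pass2",
                                      "smooth", "coherence", "seed")])
  jsonlite::write_json(rep, file.path(cfg$out_dir, "estimate.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fit)
}

#' Validate the video-derived rate against ECG
#'
#' Runs the estimator, derives the ECG ground-truth rate (R-peak detection,
#' inter-peak rate, shared 20 s running average), computes their wavelet
#' coherence and writes both series, the coherence matrix and a
#' `validate.json` report with the summary-table fields: ECG mean/s.d.,
#' video-estimate mean/s.d., BPM-difference statistics and the scalar
#' coherence coefficient.
#'
#' @param config a [pipeline_config] (or anything it accepts).
#' @param clip optional in-memory [video_clip].
#' @param ecg optional in-memory [ecg_record]; otherwise read from
#'   `config$ecg$path`.
#' @return the report list, invisibly; files under `config$out_dir`.
#' @export
run_validate <- function(config = NULL, clip = NULL, ecg = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(clip)) {
    if (is.null(cfg$video$path)) stop("no video input", call. = FALSE)
    clip <- load_video(cfg$video$path, mode = cfg$video$mode,
                       fps = cfg$video$fps)
  }
  if (is.null(ecg)) {
    if (is.null(cfg$ecg$path)) stop("no ECG input", call. = FALSE)
    ecg <- read_ecg_csv(cfg$ecg$path, fs = cfg$ecg$fs)
  }
  r <- if (!is.null(cfg$video$roi)) do.call(roi, as.list(cfg$video$roi))
  fit <- cfg_estimate(cfg, clip, roi = r)
  message(sprintf("[validate] window=%gs coherence range=[%g,%g] Hz",
                  cfg$smooth$window_s, cfg$coherence$freq_range[1],
                  cfg$coherence$freq_range[2]))
  peaks <- detect_r_peaks(ecg)
  ecg_hr <- running_average(interpeak_hr(peaks), cfg$smooth$window_s)
  tfc <- wavelet_coherence(fit$hr, ecg_hr,
                           freq_range = cfg$coherence$freq_range)
  coh <- temporal_coherence_summary(tfc, order = cfg$coherence$order)
  # pointwise BPM difference on the video time grid
  ecg_on_v <- stats::approx(ecg_hr$times, ecg_hr$bpm,
                            xout = fit$hr$times, rule = 2)$y
  ok <- fit$hr$edge_mask
  dif <- fit$hr$bpm[ok] - ecg_on_v[ok]
  rep <- list(ecg_mean = mean(ecg_hr$bpm), ecg_sd = stats::sd(ecg_hr$bpm),
              evm_mean = mean(fit$hr$bpm[ok]),
              evm_sd = stats::sd(fit$hr$bpm[ok]),
              bpm_diff_mean = mean(dif), bpm_diff_sd = stats::sd(dif),
              coherence = coh)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hr_csv(fit$hr, file.path(cfg$out_dir, "evm_hr.csv"))
  write_hr_csv(ecg_hr, file.path(cfg$out_dir, "ecg_hr.csv"))
  cm <- as.data.frame(tfc$coh)
  names(cm) <- sprintf("f_%.4gHz", tfc$freqs)
  cm <- cbind(time_s = tfc$times, cm)
  utils::write.csv(cm, file.path(cfg$out_dir, "coherence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, file.path(cfg$out_dir, "validate.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Run the spatial coherence map
#'
#' @param config a [pipeline_config].
#' @param clip,ecg optional in-memory inputs (as in [run_validate()]).
#' @return the [roi_coherence_map()] grid, invisibly; writes `map.csv`
#'   (`row,col,coherence,valid`).
#' @export
run_coherence_map <- function(config = NULL, clip = NULL, ecg = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(clip)) {
    clip <- load_video(cfg$video$path, mode = cfg$video$mode,
                       fps = cfg$video$fps)
  }
  if (is.null(ecg)) ecg <- read_ecg_csv(cfg$ecg$path, fs = cfg$ecg$fs)
  message(sprintf("[coherence-map] grid=%dx%d", cfg$coherence$grid[1],
                  cfg$coherence$grid[2]))
  peaks <- detect_r_peaks(ecg)
  ecg_hr <- running_average(interpeak_hr(peaks), cfg$smooth$window_s)
  grid <- roi_coherence_map(clip, ecg_hr, grid = cfg$coherence$grid,
                            params = cfg_params(cfg, clip$fps_nominal),
                            select_criterion = cfg$select$criterion,
                            select_fraction = cfg$select$fraction,
                            step_bpm = cfg$wavelet$step_bpm,
                            margin_bpm = cfg$pass2$margin_bpm,
                            window_s = cfg$smooth$window_s)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(row = rep(seq_len(grid$n_rows), each = grid$n_cols) - 1L,
                   col = rep(seq_len(grid$n_cols), grid$n_rows) - 1L,
                   coherence = as.vector(t(grid$values)),
                   valid = as.integer(as.vector(t(grid$valid))))
  utils::write.csv(df, file.path(cfg$out_dir, "map.csv"),
                   row.names = FALSE)
  invisible(grid)
}

#' Run the stimulus-aligned analysis
#'
#' Aligns a heart-rate series to events, baseline-corrects, and writes the
#' per-category mean +/- s.e. trace (`response_<category>.csv`) plus a
#' `events_stats.json` report (n, Wilcoxon p, Cohen's d).
#'
#' @param config a [pipeline_config].
#' @param hr optional in-memory [hr_series]; else read from the `hr.csv`
#'   in `out_dir`.
#' @param events optional in-memory [event_set]; else read from
#'   `config$events$path`.
#' @param run_sd global run s.d. for the effect size; default computed
#'   from `hr`.
#' @return list of per-category test results, invisibly.
#' @export
run_events <- function(config = NULL, hr = NULL, events = NULL,
                       run_sd = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(hr)) hr <- read_hr_csv(file.path(cfg$out_dir, "hr.csv"))
  if (is.null(events)) events <- read_events_csv(cfg$events$path)
  if (is.null(run_sd)) run_sd <- stats::sd(hr$bpm[hr$edge_mask])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (cat in unique(events$categories)) {
    resp <- align_to_events(hr, events, window = cfg$events$window,
                            category = cat)
    resp <- baseline_correct(resp, cfg$events$baseline)
    sm <- summarize_response(resp)
    tst <- pre_post_test(resp, pre = cfg$events$pre,
                         post = cfg$events$post, run_sd = run_sd)
    utils::write.csv(
      data.frame(peri_s = sm$peri_times, mean_bpm = sm$mean,
                 se_bpm = sm$se),
      file.path(cfg$out_dir, paste0("response_", cat, ".csv")),
      row.names = FALSE)
    out[[cat]] <- list(n = resp$n_trials, p_value = tst$p_value,
                       cohens_d = tst$effect_d,
                       effect = tst$effect_label)
  }
  jsonlite::write_json(out, file.path(cfg$out_dir, "events_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' End-to-end demonstration on synthetic data
#'
#' Simulates a paired video + ECG session with a known heart-rate profile,
#' then runs estimation, ECG validation, a spatial coherence map and the
#' stimulus-aligned statistics, writing every stage's outputs plus a
#' `summary.json`. Fully offline and deterministic given the seed.
#'
#' @param outdir output directory.
#' @param seed integer seed driving every stage.
#' @param duration_s,fps,size scenario scale (kept small so the demo runs
#'   in about a minute).
#' @return the summary list, invisibly.
#' @export
run_all_demo <- function(outdir, seed = 1, duration_s = 40, fps = 20,
                         size = 32) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- scenario_spec(duration_s = duration_s, fps = fps, height = size,
                        width = size, mode = "IR",
                        hr_profile = hr_sine(120, 8, 30),
                        modulation_amp = 0.01, noise_sd = 0.01,
                        seed = seed)
  ses <- synth_session(spec, ecg_noise_sd = 0.05)
  write_video(ses$video, file.path(outdir, "frames"))
  utils::write.csv(
    data.frame(time_s = (seq_along(ses$ecg$samples) - 1) / ses$ecg$fs,
               voltage = ses$ecg$samples),
    file.path(outdir, "ecg.csv"), row.names = FALSE)
  write_hr_csv(ses$truth, file.path(outdir, "truth_hr.csv"))

  cfg <- pipeline_config(list(
    video = list(mode = "IR", fps = fps),
    evm = list(levels = 3, band_bpm = c(90, 200)),
    coherence = list(grid = c(3, 3)),
    out_dir = outdir, seed = seed))
  fit <- run_estimate(cfg, clip = ses$video)
  val <- run_validate(cfg, clip = ses$video, ecg = ses$ecg)
  map <- run_coherence_map(cfg, clip = ses$video, ecg = ses$ecg)

  ev_ses <- synth_hr_session(n_trials = 20, delta_bpm = 5, trial_sd = 3,
                             seed = seed + 2)
  utils::write.csv(
    data.frame(onset_s = ev_ses$events$onsets,
               category = ev_ses$events$categories),
    file.path(outdir, "events.csv"), row.names = FALSE)
  ev <- run_events(cfg, hr = ev_ses$hr, events = ev_ses$events)

  ok <- fit$hr$edge_mask
  tr <- stats::approx(ses$truth$times, ses$truth$bpm,
                      xout = fit$hr$times, rule = 2)$y
  summary <- list(
    seed = seed,
    estimate = list(median_bpm = stats::median(fit$hr$bpm[ok]),
                    rmse_vs_truth =
                      sqrt(mean((fit$hr$bpm[ok] - tr[ok])^2))),
    validate = val,
    map = list(n_valid = sum(map$valid),
               max_coherence = max(map$values, na.rm = TRUE)),
    events = ev)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
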