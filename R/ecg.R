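#' ECG record
#'
#' Uniformly sampled single-lead ECG voltage trace.
#'
#' @param samples voltage samples, arbitrary units.
#' @param fs sampling rate, Hz (> 0); the spec-typical acquisition rate is
#'   2 kHz, high enough for a well-defined QRS waveform.
#' @param t0 time offset (seconds) of the first sample, used to synchronize
#'   with video.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (length(samples) < 2 * fs)
    stop("ECG record shorter than 2 s", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ecg_record")
}

#' Read an ECG trace from delimited text
#'
#' Accepts either a two-column CSV `time_s,voltage` (sampling rate inferred
#' from the time column) or a single voltage column with `fs` supplied.
#'
#' @param path CSV file path.
#' @param fs sampling rate, required for single-column input.
#' @return an [ecg_record].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) >= 2L) {
    dt <- stats::median(diff(df[[1]]))
    ecg_record(df[[2]], fs = 1 / dt, t0 = df[[1]][1])
  } else {
    if (is.null(fs)) stop("single-column ECG needs fs", call. = FALSE)
    ecg_record(df[[1]], fs = fs)
  }
}

#' Detect R peaks in an ECG trace
#'
#' Pan–Tompkins-style detector: 5–30 Hz Butterworth band-pass, squared
#' derivative, moving-window integration, adaptive threshold at a multiple
#' of a running amplitude estimate, then a refractory constraint. Each
#' reported time is refined to the local maximum of the band-passed signal.
#'
#' @param ecg an [ecg_record].
#' @param refractory_s minimum peak spacing, seconds (default 0.25 s,
#'   supporting rates up to 240 BPM).
#' @param threshold_frac detection threshold as a fraction of the running
#'   95th-percentile integrated amplitude (default 0.4).
#' @return strictly increasing numeric vector of peak times (seconds,
#'   including `t0`); empty for a flat record.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25, threshold_frac = 0.4) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  x <- ecg$samples
  n <- length(x)
  if (n < 2 * fs) stop("ECG record shorter than 2 s", call. = FALSE)
  if (stats::sd(x) == 0) return(numeric(0))
  bf <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x - mean(x))
  d <- c(0, diff(xb)) * fs
  e <- d^2
  # moving-window integration, ~120 ms
  wlen <- max(3L, round(0.12 * fs))
  integ <- stats::filter(e, rep(1 / wlen, wlen), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- threshold_frac * stats::quantile(integ, 0.95, names = FALSE)
  if (thr <= 0) return(numeric(0))
  above <- integ > thr
  # candidate = local maxima of the integrated energy above threshold
  cand <- which(above &
                  integ >= c(-Inf, integ[-n]) &
                  integ > c(integ[-1], -Inf))
  if (length(cand) == 0L) return(numeric(0))
  # refine each candidate to the nearby band-passed |signal| maximum
  half <- as.integer(round(0.08 * fs))
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(abs(xb[lo:hi])) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # refractory: greedy, keep the stronger of two close peaks
  keep <- logical(length(ref))
  last <- -Inf; last_i <- 0L
  for (k in seq_along(ref)) {
    tcur <- ref[k] / fs
    if (tcur - last >= refractory_s) {
      keep[k] <- TRUE; last <- tcur; last_i <- k
    } else if (abs(xb[ref[k]]) > abs(xb[ref[last_i]])) {
      keep[last_i] <- FALSE; keep[k] <- TRUE; last <- tcur; last_i <- k
    }
  }
  (ref[keep] - 1) / fs + ecg$t0
}

#' Instantaneous heart rate from R-peak times
#'
#' `bpm_i = 60 / (t_{i+1} - t_i)` placed at the midpoint of each interval.
#' Smoothing is applied separately via [running_average()] (the default
#' 20 s window shared with the video estimator).
#'
#' @param peaks strictly increasing peak times, seconds (>= 2 peaks).
#' @return an unsmoothed ECG-source [hr_series].
#' @export
interpeak_hr <- function(peaks) {
  if (length(peaks) < 2L) stop("need at least 2 peaks", call. = FALSE)
  rr <- diff(peaks)
  hr_series(peaks[-length(peaks)] + rr / 2, 60 / rr, source = "ECG",
            smoothed = FALSE)
}
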