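#' Heart-rate time series
#'
#' @param times sample times, seconds, strictly increasing.
#' @param bpm heart-rate values, beats per minute.
#' @param source `"EVM"` (video-derived) or `"ECG"`.
#' @param smoothed has a running average been applied?
#' @param edge_mask logical validity flags (`TRUE` = valid interior sample);
#'   defaults to all valid.
#' @return object of class `hr_series`.
#' @export
hr_series <- function(times, bpm, source = c("EVM", "ECG"),
                      smoothed = FALSE, edge_mask = NULL) {
  source <- match.arg(source)
  if (length(times) != length(bpm))
    stop("times and bpm must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(edge_mask)) edge_mask <- rep(TRUE, length(times))
  if (length(edge_mask) != length(times))
    stop("edge_mask length mismatch", call. = FALSE)
  if (any(bpm[edge_mask] <= 0, na.rm = TRUE))
    stop("bpm must be positive where valid", call. = FALSE)
  structure(list(times = as.numeric(times), bpm = as.numeric(bpm),
                 source = source, smoothed = isTRUE(smoothed),
                 edge_mask = as.logical(edge_mask)),
            class = "hr_series")
}

# Morlet (omega0 = 6) continuous wavelet transform evaluated at the given
# frequencies (Hz). FFT implementation with zero padding to the next power
# of two; the series mean is removed first. Returns a T x F complex matrix.
.morlet_omega0 <- 6
morlet_scale_for_freq <- function(f_hz) {
  w0 <- .morlet_omega0
  (w0 + sqrt(2 + w0^2)) / (4 * pi * f_hz)
}

cwt_morlet <- function(series, fs, freqs_hz) {
  n <- length(series)
  x <- series - mean(series)
  npad <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x, rep(0, npad - n)))
  omega <- 2 * pi * fs * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / npad
  w0 <- .morlet_omega0
  W <- matrix(0i, n, length(freqs_hz))
  dt <- 1 / fs
  for (j in seq_along(freqs_hz)) {
    s <- morlet_scale_for_freq(freqs_hz[j])
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - w0)^2 / 2)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / npad
    W[, j] <- w[seq_len(n)]
  }
  W
}

#' Wavelet power of a scalar trace over a heart-rate band
#'
#' Continuous (complex Morlet) wavelet transform magnitude squared,
#' evaluated on a regular BPM grid spanning the analysis band, with one
#' time sample per input sample.
#'
#' @param series numeric vector, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param band_bpm length-2 analysis band in BPM.
#' @param step_bpm frequency-grid step, BPM (default 0.5).
#' @param times optional sample times (default `(0:(n-1))/fs`).
#' @return object of class `tf_power`: `times` (s), `freqs_bpm`
#'   (ascending), `power` (time x frequency, >= 0), and an `edge` flag per
#'   time sample marking the cone-of-influence region (within one wavelet
#'   e-folding time — floored at 2 s for the ideal-filter edge — of either
#'   end).
#' @export
wavelet_power <- function(series, fs, band_bpm, step_bpm = 0.5,
                          times = NULL) {
  if (band_bpm[1] <= 0 || band_bpm[2] <= band_bpm[1])
    stop("band must satisfy 0 < lo < hi", call. = FALSE)
  if (fs <= 2 * band_bpm[2] / 60)
    stop("sampling rate too low for band upper edge (Nyquist)",
         call. = FALSE)
  n <- length(series)
  if (is.null(times)) times <- (seq_len(n) - 1) / fs
  if (n / fs < 3 / (band_bpm[1] / 60))
    stop("series shorter than 3 cycles of the band's low edge",
         call. = FALSE)
  freqs_bpm <- seq(band_bpm[1], band_bpm[2], by = step_bpm)
  W <- cwt_morlet(series, fs, freqs_bpm / 60)
  pw <- Mod(W)^2
  efold <- sqrt(2) * morlet_scale_for_freq(band_bpm[1] / 60)
  pad <- max(2, efold)
  edge <- times < times[1] + pad | times > times[n] - pad
  structure(list(times = times, freqs_bpm = freqs_bpm, power = pw,
                 edge = edge),
            class = "tf_power")
}

#' Peak-frequency ridge of a time-frequency power map
#'
#' Instantaneous heart rate is the frequency of maximal wavelet power at
#' each time step; ties resolve to the lowest frequency. Samples in the
#' cone-of-influence edge region, and any degenerate all-zero time step,
#' are flagged invalid in `edge_mask`.
#'
#' @param tf a [wavelet_power()] result.
#' @return an unsmoothed EVM-source [hr_series].
#' @export
peak_frequency_track <- function(tf) {
  stopifnot(inherits(tf, "tf_power"))
  idx <- max.col(tf$power, ties.method = "first")
  bpm <- tf$freqs_bpm[idx]
  dead <- rowSums(tf$power) <= 0
  valid <- !tf$edge & !dead
  bpm[dead] <- NA_real_
  hr_series(tf$times, ifelse(is.na(bpm), tf$freqs_bpm[1], bpm),
            source = "EVM", smoothed = FALSE, edge_mask = valid)
}

#' Running average of a heart-rate series
#'
#' Centered moving mean over the valid samples within `window_s / 2` of
#' each time point, truncated at the series edges.
#'
#' @param series an [hr_series].
#' @param window_s averaging window length, seconds (default 20).
#' @return the smoothed [hr_series] (`smoothed = TRUE`).
#' @export
running_average <- function(series, window_s = 20) {
  stopifnot(inherits(series, "hr_series"))
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  tt <- series$times
  half <- window_s / 2
  valid <- series$edge_mask & !is.na(series$bpm)
  vt <- tt[valid]; vb <- series$bpm[valid]
  out <- vapply(tt, function(t0) {
    sel <- vt >= t0 - half & vt <= t0 + half
    if (any(sel)) mean(vb[sel]) else NA_real_
  }, numeric(1))
  out[is.na(out)] <- series$bpm[is.na(out)]
  hr_series(tt, out, source = series$source, smoothed = TRUE,
            edge_mask = series$edge_mask)
}

#' Select informative pixels of a clip
#'
#' Ranks pixels either by temporal-mean intensity (`"luminosity"`) or by
#' temporal DFT power inside the heart-rate band (`"band_power"`), averaged
#' across channels, and returns a mask of the top `ceil(fraction * N)`
#' pixels. Ties break deterministically in (row, col) order.
#'
#' @param clip a [video_clip].
#' @param criterion `"band_power"` (default) or `"luminosity"`.
#' @param fraction proportion of pixels to keep, in `(0, 1]` (default 0.1).
#' @param band_bpm BPM band for the `band_power` criterion.
#' @return logical `H x W` mask.
#' @export
select_pixels <- function(clip, criterion = c("band_power", "luminosity"),
                          fraction = 0.1, band_bpm = c(90, 200)) {
  stopifnot(inherits(clip, "video_clip"))
  criterion <- match.arg(criterion)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  hw <- frame_dim(clip)
  nt <- n_frames(clip)
  if (nt == 0L) stop("empty clip", call. = FALSE)
  npix <- prod(hw)
  nc <- n_channels(clip)
  score <- matrix(0, hw[1], hw[2])
  if (criterion == "luminosity") {
    for (ch in seq_len(nc)) {
      m <- matrix(clip$frames[, , ch, ], nrow = npix)
      score <- score + matrix(rowMeans(m), hw[1], hw[2])
    }
  } else {
    fs <- clip$fps_nominal
    f <- (seq_len(nt) - 1) * fs / nt
    f <- pmin(f, fs - f)
    keep <- f >= band_bpm[1] / 60 & f <= band_bpm[2] / 60
    for (ch in seq_len(nc)) {
      m <- t(matrix(clip$frames[, , ch, ], nrow = npix))  # T x pixels
      sp <- stats::mvfft(m)
      score <- score +
        matrix(colSums(Mod(sp[keep, , drop = FALSE])^2), hw[1], hw[2])
    }
  }
  k <- ceiling(fraction * npix)
  sv <- as.vector(t(score))                 # row-major flatten
  ord <- order(-sv)                          # stable: ties in (row,col) order
  mask <- matrix(FALSE, hw[1], hw[2])
  sel <- ord[seq_len(k)]
  mask[cbind((sel - 1) %/% hw[2] + 1, (sel - 1) %% hw[2] + 1)] <- TRUE
  mask
}

#' Refine the analysis band around a first-pass estimate
#'
#' Second-pass band `[hr_approx - margin, hr_approx + margin]`, intersected
#' with the global physiological band.
#'
#' @param hr_approx first-pass heart-rate approximation, BPM.
#' @param margin half-width of the refined band, BPM (default 10).
#' @param global_band physiological band the result is clamped to.
#' @return length-2 numeric band in BPM.
#' @export
refine_band <- function(hr_approx, margin = 10, global_band = c(90, 200)) {
  if (hr_approx <= margin)
    stop("hr_approx must exceed the margin", call. = FALSE)
  lo <- max(hr_approx - margin, global_band[1])
  hi <- min(hr_approx + margin, global_band[2])
  if (hi <= lo)
    stop("refined band is empty after clamping to the global band",
         call. = FALSE)
  c(lo, hi)
}

#' Two-pass video heart-rate estimation
#'
#' The central fitting routine. Pass 1 magnifies the region of interest over
#' a broad physiological band, averages the most informative pixels (and all
#' channels) into one trace, and reads a first heart-rate approximation off
#' the Morlet wavelet ridge (median of the interior instantaneous
#' estimates). Pass 2 repeats the magnification with a narrow band centred
#' on that approximation and returns the running-average of the refined
#' ridge.
#'
#' The pass-2 half-width is widened automatically when the pass-1 ridge
#' wanders beyond `margin_bpm` of its median, so a drifting heart rate is
#' never clipped by the refined band (disable with `adaptive_margin =
#' FALSE`).
#'
#' @param clip a time-uniform [video_clip].
#' @param roi optional [roi] to crop to first.
#' @param params an [evm_params]; its `band_bpm` is the broad pass-1 band
#'   and the global physiological band.
#' @param select_criterion,select_fraction pixel selection, see
#'   [select_pixels()].
#' @param step_bpm wavelet frequency-grid step, BPM.
#' @param margin_bpm minimal pass-2 half-width, BPM.
#' @param adaptive_margin widen the margin to cover pass-1 excursions?
#' @param window_s running-average window, seconds.
#' @return object of class `evm_hr`: the smoothed series (`$hr`), the raw
#'   pass-2 ridge (`$track`), pass-1 provenance (`$pass1$hr_approx`,
#'   `$pass1$track`), the refined band (`$band2`), the pixel mask and the
#'   parameters used.
#' @export
estimate_hr <- function(clip, roi = NULL, params = NULL,
                        select_criterion = c("band_power", "luminosity"),
                        select_fraction = 0.1, step_bpm = 0.5,
                        margin_bpm = 10, adaptive_margin = TRUE,
                        window_s = 20) {
  stopifnot(inherits(clip, "video_clip"))
  select_criterion <- match.arg(select_criterion)
  if (!is.null(roi)) clip <- crop_roi(clip, roi)
  dts <- diff(clip$timestamps)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    clip <- resample_uniform(clip, clip$fps_nominal)
  fs <- 1 / stats::median(diff(clip$timestamps))
  if (is.null(params)) params <- evm_params(fps = fs)
  band1 <- params$band_bpm
  dur <- diff(range(clip$timestamps))
  if (dur < 3 / (band1[1] / 60))
    stop("clip shorter than 3 cycles of the band's low edge", call. = FALSE)
  # cap pyramid depth to the geometry (small ROI cells)
  lv <- min(params$levels, floor(log2(min(frame_dim(clip)))) - 1L)
  lv <- max(lv, 1L)
  p1 <- evm_params(params$alpha, band1, lv, fps = fs)

  mag1 <- magnify(clip, p1)
  mask <- select_pixels(mag1, select_criterion, select_fraction,
                        band_bpm = band1)
  tr1 <- colMeans(channel_mean_series(mag1, mask))
  tf1 <- wavelet_power(tr1, fs, band1, step_bpm, times = clip$timestamps)
  track1 <- peak_frequency_track(tf1)
  int1 <- track1$edge_mask
  if (!any(int1)) stop("no interior samples in pass 1", call. = FALSE)
  hr_approx <- stats::median(track1$bpm[int1])

  margin <- margin_bpm
  if (adaptive_margin) {
    # widen to cover pass-1 excursions plus ~30% sideband room: a drifting
    # rate is frequency-modulated, and its spectrum extends beyond the
    # instantaneous-frequency range (Carson's rule), so a band cut at the
    # bare excursion would clip the modulation it is meant to keep
    excursion <- max(abs(track1$bpm[int1] - hr_approx))
    margin <- max(margin_bpm, 1.3 * excursion + 2 * step_bpm)
  }
  band2 <- refine_band(hr_approx, margin, global_band = band1)

  p2 <- evm_params(params$alpha, band2, lv, fps = fs)
  mag2 <- magnify(clip, p2)
  tr2 <- colMeans(channel_mean_series(mag2, mask))
  tf2 <- wavelet_power(tr2, fs, band2, step_bpm, times = clip$timestamps)
  track2 <- peak_frequency_track(tf2)
  hr <- running_average(track2, window_s)

  structure(list(
    hr = hr, track = track2, band2 = band2,
    pass1 = list(hr_approx = hr_approx, track = track1, band = band1,
                 margin_used = margin),
    mask = mask, params = p1,
    opts = list(select_criterion = select_criterion,
                select_fraction = select_fraction, step_bpm = step_bpm,
                margin_bpm = margin_bpm, adaptive_margin = adaptive_margin,
                window_s = window_s)),
    class = "evm_hr")
}
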