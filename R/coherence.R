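#' Wavelet coherence between two heart-rate series
#'
#' Squared wavelet coherence `|S(Wx Wy* / s)|^2 / (S(|Wx|^2/s) S(|Wy|^2/s))`
#' with a smoothing operator `S` acting over time (boxcar of one wavelet
#' period per scale) and over scale (boxcar spanning 0.6 octaves). Without
#' smoothing, pointwise coherence would be identically 1; the smoothing is
#' what makes the estimator informative. Both series are linearly resampled
#' to a common uniform grid (default 1 Hz — heart rate varies slowly, and
#' its fluctuations live below 0.5 Hz) over their overlapping support.
#'
#' @param x,y [hr_series] objects with overlapping time support.
#' @param freq_range length-2 frequency range of interest in Hz; the lower
#'   edge is clamped so that at least two cycles fit in the overlap.
#' @param fs common resampling rate, Hz.
#' @param dj frequency-grid spacing, octaves.
#' @return object of class `tf_coherence`: `times` (s), `freqs` (Hz,
#'   ascending), `coh` (time x frequency in `[0, 1]`), and `valid`
#'   (logical matrix marking points outside each scale's cone of
#'   influence).
#' @export
wavelet_coherence <- function(x, y, freq_range = c(0.02, 0.5), fs = 1,
                              dj = 0.1) {
  stopifnot(inherits(x, "hr_series"), inherits(y, "hr_series"))
  t0 <- max(min(x$times), min(y$times))
  t1 <- min(max(x$times), max(y$times))
  if (t1 - t0 < 10)
    stop("series overlap shorter than 10 s", call. = FALSE)
  times <- seq(t0, t1, by = 1 / fs)
  xi <- stats::approx(x$times, x$bpm, xout = times, rule = 2)$y
  yi <- stats::approx(y$times, y$bpm, xout = times, rule = 2)$y
  dur <- t1 - t0
  f_lo <- max(freq_range[1], 2 / dur)
  f_hi <- min(freq_range[2], fs / 2 * 0.99)
  if (f_hi <= f_lo)
    stop("empty frequency range after clamping to the overlap",
         call. = FALSE)
  n_oct <- log2(f_hi / f_lo)
  freqs <- f_lo * 2^(seq(0, n_oct, by = dj))
  Wx <- cwt_morlet(xi, fs, freqs)
  Wy <- cwt_morlet(yi, fs, freqs)
  scales <- morlet_scale_for_freq(freqs)
  sw <- matrix(scales, nrow = length(times), ncol = length(freqs),
               byrow = TRUE)
  cross <- Wx * Conj(Wy) / sw
  px <- Mod(Wx)^2 / sw
  py <- Mod(Wy)^2 / sw
  s_cross <- smooth_tf(cross, freqs, fs, dj)
  s_px <- smooth_tf(px, freqs, fs, dj)
  s_py <- smooth_tf(py, freqs, fs, dj)
  coh <- Mod(s_cross)^2 / pmax(Re(s_px) * Re(s_py), .Machine$double.eps)
  coh <- pmin(pmax(coh, 0), 1)
  # cone of influence: within one e-folding time of either end, per scale
  efold <- sqrt(2) * scales
  dist_edge <- pmin(times - t0, t1 - times)
  valid <- outer(dist_edge, efold, ">")
  structure(list(times = times, freqs = freqs, coh = coh, valid = valid),
            class = "tf_coherence")
}

# smoothing operator: boxcar in time (one wavelet period per scale) then
# boxcar across 0.6 octaves in scale; edge-normalized running means
smooth_tf <- function(M, freqs, fs, dj) {
  n <- nrow(M)
  for (j in seq_along(freqs)) {
    L <- max(1L, round(fs / freqs[j]))
    if (L > 1L) M[, j] <- runmean_edge(M[, j], min(L, n))
  }
  K <- max(1L, round(0.6 / dj))
  if (K > 1L && length(freqs) > 1L) {
    M <- t(apply(M, 1, runmean_edge, L = min(K, length(freqs))))
  }
  M
}

# centered running mean with truncated edges (complex-safe)
runmean_edge <- function(v, L) {
  n <- length(v)
  hl <- L %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hl, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Scalar temporal-coherence summary
#'
#' Default reading: at each time point take the maximum squared coherence
#' across frequencies, then average these maxima over time
#' (`"max_then_mean"`). The alternative reading — per-frequency maxima over
#' time, averaged across frequencies — is available as
#' `"mean_of_freq_maxima"`. Cone-of-influence points are excluded when the
#' object carries a validity mask.
#'
#' @param tfc a [wavelet_coherence()] result (or any `tf_coherence`).
#' @param order summary order, see above.
#' @param interior_only drop cone-of-influence points?
#' @return scalar in `[0, 1]`.
#' @export
temporal_coherence_summary <- function(tfc,
                                       order = c("max_then_mean",
                                                 "mean_of_freq_maxima"),
                                       interior_only = TRUE) {
  stopifnot(inherits(tfc, "tf_coherence"))
  order <- match.arg(order)
  coh <- tfc$coh
  if (interior_only && !is.null(tfc$valid)) {
    coh[!tfc$valid] <- NA_real_
  }
  if (order == "max_then_mean") {
    mx <- apply(coh, 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    mean(mx, na.rm = TRUE)
  } else {
    mx <- apply(coh, 2, function(cl)
      if (all(is.na(cl))) NA_real_ else max(cl, na.rm = TRUE))
    mean(mx, na.rm = TRUE)
  }
}

#' Spatial ROI coherence map
#'
#' Tiles the frame into a grid of independent regions of interest
#' (remainder pixels going to the last row/column), runs the full two-pass
#' heart-rate estimator on each cell, and stores the scalar temporal
#' coherence of the cell's estimate against the ECG-derived rate. Cells too
#' small for the pyramid, or whose estimate fails, are flagged invalid
#' rather than aborting the map.
#'
#' @param clip a [video_clip] overlapping `ecg_hr` in time.
#' @param ecg_hr the ECG-derived (smoothed) [hr_series].
#' @param grid length-2 integer grid shape `c(n_rows, n_cols)`, default
#'   `c(10, 10)`.
#' @param params an [evm_params] for the per-cell estimator.
#' @param min_cell_px minimal cell side length, pixels.
#' @param ... passed on to [estimate_hr()].
#' @return object of class `coherence_grid`: `values` and `valid`
#'   (n_rows x n_cols matrices), `cells` (list of [roi] bounds),
#'   `n_rows`, `n_cols`.
#' @export
roi_coherence_map <- function(clip, ecg_hr, grid = c(10, 10), params = NULL,
                              min_cell_px = 4, ...) {
  stopifnot(inherits(clip, "video_clip"), inherits(ecg_hr, "hr_series"))
  nr <- as.integer(grid[1]); ncg <- as.integer(grid[2])
  hw <- frame_dim(clip)
  rb <- floor(seq(0, hw[1], length.out = nr + 1))
  cb <- floor(seq(0, hw[2], length.out = ncg + 1))
  rb[nr + 1] <- hw[1]; cb[ncg + 1] <- hw[2]   # remainder to last row/col
  values <- matrix(NA_real_, nr, ncg)
  valid <- matrix(FALSE, nr, ncg)
  cells <- vector("list", nr * ncg)
  for (i in seq_len(nr)) {
    for (j in seq_len(ncg)) {
      cell <- roi(rb[i], cb[j], rb[i + 1], cb[j + 1])
      cells[[(i - 1) * ncg + j]] <- cell
      if (cell$row1 - cell$row0 < min_cell_px ||
          cell$col1 - cell$col0 < min_cell_px) next
      fit <- tryCatch(
        estimate_hr(clip, roi = cell, params = params, ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      tfc <- tryCatch(wavelet_coherence(fit$hr, ecg_hr),
                      error = function(e) NULL)
      if (is.null(tfc)) next
      values[i, j] <- temporal_coherence_summary(tfc)
      valid[i, j] <- is.finite(values[i, j])
    }
  }
  structure(list(values = values, valid = valid, cells = cells,
                 n_rows = nr, n_cols = ncg),
            class = "coherence_grid")
}
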