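#' Eulerian video magnification parameters
#'
#' Bundles the gain, temporal pass-band and pyramid depth for [magnify()].
#' The pass-band is given in beats per minute and converted to Hz (/60)
#' internally; it must lie below the Nyquist rate of the clip.
#'
#' @param alpha amplification gain \eqn{\alpha \ge 0} (dimensionless). The
#'   amplified clip carries in-band modulation scaled by \eqn{1 + \alpha}.
#' @param band_bpm length-2 numeric, temporal pass-band `[lo, hi]` in BPM;
#'   default `c(90, 200)`, the expected physiological heart-rate range.
#' @param levels Gaussian-pyramid depth (>= 1); amplification is applied at
#'   the coarsest level.
#' @param fps frame rate of the (uniform) clip the parameters will be
#'   applied to, frames/second.
#' @return object of class `evm_params`.
#' @export
evm_params <- function(alpha = 50, band_bpm = c(90, 200), levels = 4,
                       fps = 30) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single number >= 0", call. = FALSE)
  if (length(band_bpm) != 2L || band_bpm[1] <= 0 ||
      band_bpm[2] <= band_bpm[1])
    stop("band_bpm must satisfy 0 < lo < hi", call. = FALSE)
  if (band_bpm[2] / 60 >= fps / 2)
    stop("pass-band upper edge ", band_bpm[2], " BPM is at or above the ",
         "Nyquist rate for fps = ", fps, call. = FALSE)
  if (levels < 1 || levels != floor(levels))
    stop("levels must be an integer >= 1", call. = FALSE)
  structure(list(alpha = alpha, band_bpm = as.numeric(band_bpm),
                 levels = as.integer(levels), fps = fps),
            class = "evm_params")
}

# 5-tap binomial kernel [1,4,6,4,1]/16 -- the standard pyramid blur
.pyr_kernel <- c(1, 4, 6, 4, 1) / 16

# separable blur along dim 1 of a (H x W x T) array, replicate padding;
# vectorized as shifted row sums on the H x (W*T) matrix view
blur_rows <- function(a) {
  d <- dim(a); h <- d[1]
  m <- matrix(a, nrow = h)
  r <- seq_len(h)
  k <- .pyr_kernel
  out <- k[3] * m
  out <- out + k[1] * m[pmax(r - 2L, 1L), , drop = FALSE]
  out <- out + k[2] * m[pmax(r - 1L, 1L), , drop = FALSE]
  out <- out + k[4] * m[pmin(r + 1L, h), , drop = FALSE]
  out <- out + k[5] * m[pmin(r + 2L, h), , drop = FALSE]
  array(out, dim = d)
}

blur_hw <- function(a) {
  a <- blur_rows(a)
  a <- aperm(a, c(2, 1, 3))
  a <- blur_rows(a)
  aperm(a, c(2, 1, 3))
}

# one pyramid level: blur then keep every 2nd row/col (1, 3, 5, ...)
pyr_down1 <- function(a) {
  a <- blur_hw(a)
  d <- dim(a)
  a[seq(1L, d[1], by = 2L), seq(1L, d[2], by = 2L), , drop = FALSE]
}

# bilinear resize of (h x w x T) to (th x tw x T) via separable
# interpolation matrices; clamped at the borders, so constants are preserved
resize_bilinear <- function(a, th, tw) {
  d <- dim(a)
  Rm <- interp_matrix(d[1], th)
  Cm <- interp_matrix(d[2], tw)
  m <- Rm %*% matrix(a, nrow = d[1])                     # th x (w*T)
  m <- array(m, dim = c(th, d[2], d[3]))
  m <- aperm(m, c(2, 1, 3))
  m <- Cm %*% matrix(m, nrow = d[2])                     # tw x (th*T)
  aperm(array(m, dim = c(tw, th, d[3])), c(2, 1, 3))
}

# n_out x n_in linear-interpolation matrix, pixel-center aligned
interp_matrix <- function(n_in, n_out) {
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5 - 1  # 0-based coord
  lo <- floor(pos)
  w_hi <- pos - lo
  lo <- pmin(pmax(lo, 0), n_in - 1)
  hi <- pmin(lo + 1, n_in - 1)
  M <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  M[cbind(idx, lo + 1)] <- M[cbind(idx, lo + 1)] + (1 - w_hi)
  M[cbind(idx, hi + 1)] <- M[cbind(idx, hi + 1)] + w_hi
  M
}

#' Gaussian-pyramid spatial downsampling
#'
#' Each level applies a small separable Gaussian (binomial 5-tap) blur and a
#' factor-2 decimation; the clip returned is the coarsest level.
#' `levels = 0` is the identity by convention.
#'
#' @param clip a [video_clip].
#' @param levels number of blur-and-decimate steps (>= 0).
#' @return the downsampled [video_clip]; timestamps unchanged.
#' @export
gaussian_downsample <- function(clip, levels) {
  stopifnot(inherits(clip, "video_clip"))
  if (levels < 0 || levels != floor(levels))
    stop("levels must be a non-negative integer", call. = FALSE)
  if (levels == 0L) return(clip)
  hw <- frame_dim(clip)
  if (min(hw) < 2^levels)
    stop("frames of ", hw[1], " x ", hw[2], " too small for ", levels,
         " pyramid levels", call. = FALSE)
  nc <- n_channels(clip)
  chans <- vector("list", nc)
  for (ch in seq_len(nc)) {
    a <- clip$frames[, , ch, , drop = TRUE]
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)  # T = 1 guard
    for (l in seq_len(levels)) a <- pyr_down1(a)
    chans[[ch]] <- a
  }
  d <- dim(chans[[1]])
  frames <- array(0, dim = c(d[1], d[2], nc, d[3]))
  for (ch in seq_len(nc)) frames[, , ch, ] <- chans[[ch]]
  video_clip(frames, clip$timestamps, mode = clip$mode,
             fps_nominal = clip$fps_nominal)
}

#' Ideal (brick-wall) temporal band-pass filter
#'
#' Retains DFT components with `|f|` in `[f_lo, f_hi]` at unit gain and
#' zeroes all others. Zero-phase by construction; the output is real and has
#' the same length as the input. Finite-window spectral leakage at the
#' sequence edges is inherent to the ideal filter and accepted.
#'
#' @param series numeric vector, uniformly sampled, length >= 4.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @return filtered numeric vector of the same length.
#' @export
ideal_bandpass <- function(series, fs, f_lo, f_hi) {
  if (length(series) < 4L) stop("series too short", call. = FALSE)
  if (f_lo <= 0 || f_hi <= f_lo || f_hi >= fs / 2)
    stop("band must satisfy 0 < f_lo < f_hi < fs/2", call. = FALSE)
  drop(bandpass_mat(matrix(series, ncol = 1), fs, f_lo, f_hi))
}

# brick-wall band-pass along columns of a T x P matrix
bandpass_mat <- function(m, fs, f_lo, f_hi) {
  n <- nrow(m)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # folded (two-sided) frequency
  keep <- f >= f_lo - 1e-12 & f <= f_hi + 1e-12
  sp <- stats::mvfft(m)
  sp[!keep, ] <- 0
  Re(stats::mvfft(sp, inverse = TRUE)) / n
}

#' Eulerian video magnification
#'
#' Amplifies in-band temporal intensity variation: the clip is spatially
#' low-passed by a Gaussian pyramid, the coarsest level is temporally
#' band-passed by an ideal filter, and `alpha` times that component —
#' upsampled back to full resolution by repeated factor-2 bilinear
#' interpolation — is added to the input. In-band modulation is thereby
#' scaled by `1 + alpha`; out-of-band content passes through unchanged.
#'
#' @param clip a time-uniform [video_clip].
#' @param params an [evm_params] object valid for the clip's rate and size.
#' @param clip_output if `TRUE`, clamp the result to `[0, 1]` (export);
#'   the default `FALSE` keeps unclipped values so that linearity holds
#'   internally.
#' @return the magnified [video_clip].
#' @export
magnify <- function(clip, params, clip_output = FALSE) {
  stopifnot(inherits(clip, "video_clip"), inherits(params, "evm_params"))
  nt <- n_frames(clip)
  if (nt < 4L) stop("clip too short to magnify", call. = FALSE)
  dts <- diff(clip$timestamps)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("clip must be uniformly sampled; run resample_uniform() first",
         call. = FALSE)
  fs <- 1 / stats::median(dts)
  if (params$band_bpm[2] / 60 >= fs / 2)
    stop("pass-band above Nyquist for this clip", call. = FALSE)
  hw <- frame_dim(clip)
  if (min(hw) < 2^params$levels)
    stop("frames too small for ", params$levels, " pyramid levels",
         call. = FALSE)
  f_lo <- params$band_bpm[1] / 60
  f_hi <- params$band_bpm[2] / 60
  nc <- n_channels(clip)
  out <- clip$frames
  for (ch in seq_len(nc)) {
    a <- clip$frames[, , ch, , drop = TRUE]
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    sizes <- list(dim(a)[1:2])
    for (l in seq_len(params$levels)) {
      a <- pyr_down1(a)
      sizes[[l + 1L]] <- dim(a)[1:2]
    }
    d <- dim(a)
    m <- t(matrix(a, nrow = d[1] * d[2]))        # T x pixels
    m <- bandpass_mat(m, fs, f_lo, f_hi)
    band <- array(t(m), dim = d)
    for (l in rev(seq_len(params$levels))) {     # repeated x2 upsampling
      sz <- sizes[[l]]
      band <- resize_bilinear(band, sz[1], sz[2])
    }
    out[, , ch, ] <- out[, , ch, ] + params$alpha * band
  }
  if (clip_output) out <- pmin(pmax(out, 0), 1)
  cl <- video_clip(pmin(pmax(out, 0), 1), clip$timestamps,
                   mode = clip$mode, fps_nominal = clip$fps_nominal)
  cl$frames <- out   # internal values stay unclipped to preserve linearity
  cl
}

#' @export
print.evm_params <- function(x, ...) {
  cat(sprintf(
    "<evm_params> alpha = %g, band = [%g, %g] BPM, levels = %d, fps = %g\n",
    x$alpha, x$band_bpm[1], x$band_bpm[2], x$levels, x$fps))
  invisible(x)
}
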