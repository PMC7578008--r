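#' Construct a video clip
#'
#' A `video_clip` is the in-memory container for a video: an `H x W x C x T`
#' array of intensities in `[0, 1]` plus one timestamp (seconds) per frame.
#' `C = 3` for RGB recordings, `C = 1` for single-channel infrared (IR).
#'
#' @param frames numeric array of dimension `H x W x C x T` (or `H x W x T`
#'   for single-channel input, reshaped internally), values in `[0, 1]`.
#' @param timestamps numeric vector of per-frame times in seconds, strictly
#'   increasing, length `T`.
#' @param mode `"RGB"` or `"IR"`; must match the channel count.
#' @param fps_nominal nominal frame rate in frames/second (used when
#'   timestamps have to be synthesized and as metadata otherwise).
#'
#' @return an object of class `video_clip` with fields `frames`,
#'   `timestamps`, `mode`, `fps_nominal`.
#' @export
video_clip <- function(frames, timestamps, mode = c("RGB", "IR"),
                       fps_nominal = NULL) {
  mode <- match.arg(mode)
  if (length(dim(frames)) == 3L) {
    # H x W x T single-channel shorthand
    dim(frames) <- c(dim(frames)[1:2], 1L, dim(frames)[3])
  }
  if (length(dim(frames)) != 4L)
    stop("`frames` must be an H x W x C x T array", call. = FALSE)
  d <- dim(frames)
  nc <- d[3]; nt <- d[4]
  if (nt == 0L) stop("clip has zero frames", call. = FALSE)
  if (mode == "RGB" && nc != 3L)
    stop("RGB mode requires C = 3 channels, got ", nc, call. = FALSE)
  if (mode == "IR" && nc != 1L)
    stop("IR mode requires C = 1 channel, got ", nc, call. = FALSE)
  if (length(timestamps) != nt)
    stop("need one timestamp per frame", call. = FALSE)
  if (nt > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  rng <- range(frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("intensities must lie in [0, 1]; normalize on load", call. = FALSE)
  if (is.null(fps_nominal)) {
    fps_nominal <- if (nt > 1L) (nt - 1) / diff(range(timestamps)) else NA_real_
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         mode = mode, fps_nominal = fps_nominal),
    class = "video_clip")
}

#' Rectangular region of interest
#'
#' Pixel rectangle in 0-based, half-open convention:
#' rows `[row0, row1)`, columns `[col0, col1)`.
#'
#' @param row0,col0,row1,col1 integer pixel bounds, `0 <= row0 < row1`,
#'   `0 <= col0 < col1`.
#' @return object of class `roi`.
#' @export
roi <- function(row0, col0, row1, col1) {
  v <- c(row0 = row0, col0 = col0, row1 = row1, col1 = col1)
  if (any(v != floor(v))) stop("ROI bounds must be integers", call. = FALSE)
  if (row0 < 0 || col0 < 0 || row1 <= row0 || col1 <= col0)
    stop("invalid ROI: need 0 <= row0 < row1 and 0 <= col0 < col1",
         call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "roi")
}

n_frames <- function(clip) dim(clip$frames)[4]
frame_dim <- function(clip) dim(clip$frames)[1:2]
n_channels <- function(clip) dim(clip$frames)[3]

#' Load a video from a directory of PNG frames
#'
#' Reads a directory of frames named `frame_000001.png`, ... in
#' lexicographic order. Timestamps come from a sidecar plain-text file
#' (one seconds-value per line, same order as the frames) when present,
#' otherwise they are synthesized from `fps`. 8/16-bit PNGs are normalized
#' to `[0, 1]` by the PNG reader.
#'
#' @param path directory containing the PNG frames.
#' @param mode `"RGB"` or `"IR"`. IR accepts grayscale PNGs or collapses a
#'   gray RGB PNG to its first channel.
#' @param fps nominal frame rate used when no timestamps file exists.
#' @param timestamps_file sidecar file name relative to `path`.
#' @return a [video_clip].
#' @export
load_video <- function(path, mode = c("RGB", "IR"), fps = 30,
                       timestamps_file = "timestamps.txt") {
  mode <- match.arg(mode)
  if (!dir.exists(path))
    stop("not a readable frame directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no frames found in ", path, call. = FALSE)
  imgs <- lapply(files, png::readPNG)
  dims <- vapply(imgs, function(im) {
    d <- dim(im); c(d[1], d[2], if (length(d) == 3L) d[3] else 1L)
  }, numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes across PNG frames", call. = FALSE)
  h <- dims[1, 1]; w <- dims[2, 1]; nt <- length(imgs)
  nc <- if (mode == "RGB") 3L else 1L
  frames <- array(0, dim = c(h, w, nc, nt))
  for (i in seq_len(nt)) {
    im <- imgs[[i]]
    if (length(dim(im)) == 2L) im <- array(im, dim = c(h, w, 1L))
    if (mode == "RGB") {
      if (dim(im)[3] < 3L) stop("RGB mode but grayscale frame: ", files[i],
                                call. = FALSE)
      frames[, , , i] <- im[, , 1:3]
    } else {
      frames[, , 1L, i] <- im[, , 1L]
    }
  }
  ts_path <- file.path(path, timestamps_file)
  if (file.exists(ts_path)) {
    timestamps <- as.numeric(readLines(ts_path))
    if (length(timestamps) != nt)
      stop("timestamps file length does not match frame count", call. = FALSE)
  } else {
    timestamps <- (seq_len(nt) - 1) / fps
  }
  video_clip(frames, timestamps, mode = mode, fps_nominal = fps)
}

#' Write a clip as lossless PNG frames
#'
#' Inverse of [load_video()]: writes `frame_%06d.png` plus a sidecar
#' timestamps file. Intensities are clipped to `[0, 1]` on export.
#'
#' @param clip a [video_clip].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_video <- function(clip, path) {
  stopifnot(inherits(clip, "video_clip"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- n_frames(clip)
  for (i in seq_len(nt)) {
    fr <- clip$frames[, , , i, drop = TRUE]
    fr <- pmin(pmax(fr, 0), 1)
    png::writePNG(fr, file.path(path, sprintf("frame_%06d.png", i)))
  }
  writeLines(format(clip$timestamps, digits = 15),
             file.path(path, "timestamps.txt"))
  invisible(path)
}

#' Resample a clip onto a uniform time grid
#'
#' Consumer cameras deliver variable frame timing; frequency analysis needs
#' a uniform grid. Each output sample is the input frame with the nearest
#' timestamp (no interpolation, so raw sensor values are preserved for the
#' magnification step); ties go to the earlier frame.
#'
#' @param clip a [video_clip] with at least 2 frames.
#' @param fps_target target rate, frames/second.
#' @return a uniform [video_clip] spanning the input's time range.
#' @export
resample_uniform <- function(clip, fps_target) {
  stopifnot(inherits(clip, "video_clip"))
  if (!is.numeric(fps_target) || fps_target <= 0)
    stop("fps_target must be > 0", call. = FALSE)
  nt <- n_frames(clip)
  if (nt < 2L) stop("need >= 2 frames to resample", call. = FALSE)
  t0 <- clip$timestamps[1]; t1 <- clip$timestamps[nt]
  grid <- seq(t0, t1, by = 1 / fps_target)
  if (length(grid) < 2L) grid <- c(t0, t1)
  idx <- nearest_index(clip$timestamps, grid)
  video_clip(clip$frames[, , , idx, drop = FALSE], grid,
             mode = clip$mode, fps_nominal = fps_target)
}

# index of nearest element of `x` (sorted) for each query; ties -> earlier
nearest_index <- function(x, q) {
  lo <- findInterval(q, x, all.inside = TRUE)
  hi <- pmin(lo + 1L, length(x))
  d_lo <- abs(q - x[lo]); d_hi <- abs(x[hi] - q)
  ifelse(d_hi < d_lo, hi, lo)
}

#' Crop a clip to a region of interest
#'
#' @param clip a [video_clip].
#' @param roi an [roi] rectangle within frame bounds.
#' @return the cropped [video_clip]; timestamps unchanged.
#' @export
crop_roi <- function(clip, roi) {
  stopifnot(inherits(clip, "video_clip"), inherits(roi, "roi"))
  hw <- frame_dim(clip)
  if (roi$row1 > hw[1] || roi$col1 > hw[2])
    stop("ROI exceeds frame bounds (", hw[1], " x ", hw[2], ")",
         call. = FALSE)
  rows <- (roi$row0 + 1L):roi$row1
  cols <- (roi$col0 + 1L):roi$col1
  video_clip(clip$frames[rows, cols, , , drop = FALSE], clip$timestamps,
             mode = clip$mode, fps_nominal = clip$fps_nominal)
}

#' Per-channel mean intensity over a pixel mask
#'
#' @param clip a [video_clip].
#' @param mask logical `H x W` matrix selecting at least one pixel; `NULL`
#'   selects all pixels.
#' @return numeric matrix `C x T`: one mean-intensity series per channel.
#' @export
channel_mean_series <- function(clip, mask = NULL) {
  stopifnot(inherits(clip, "video_clip"))
  hw <- frame_dim(clip)
  if (is.null(mask)) mask <- matrix(TRUE, hw[1], hw[2])
  if (!is.logical(mask) || !all(dim(mask) == hw))
    stop("mask must be a logical H x W matrix", call. = FALSE)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  nc <- n_channels(clip); nt <- n_frames(clip)
  out <- matrix(0, nc, nt)
  midx <- which(mask)
  npix <- prod(hw)
  for (ch in seq_len(nc)) {
    m <- matrix(clip$frames[, , ch, ], nrow = npix)  # pixels x T
    out[ch, ] <- colMeans(m[midx, , drop = FALSE])
  }
  out
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d x %d px, %d channel(s) [%s], %d frames\n",
              d[1], d[2], d[3], x$mode, d[4]))
  cat(sprintf("  time %.3f .. %.3f s, nominal %.3g fps\n",
              x$timestamps[1], x$timestamps[d[4]], x$fps_nominal))
  invisible(x)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows [%d,%d) x cols [%d,%d)\n",
              x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}
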