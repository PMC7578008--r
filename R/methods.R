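#' @export
print.hr_series <- function(x, ...) {
  ok <- x$edge_mask
  cat(sprintf("<hr_series> %s%s, %d samples (%d valid), %.1f .. %.1f s\n",
              x$source, if (x$smoothed) " (smoothed)" else "",
              length(x$times), sum(ok),
              min(x$times), max(x$times)))
  if (any(ok))
    cat(sprintf("  rate: median %.1f BPM, range [%.1f, %.1f]\n",
                stats::median(x$bpm[ok]), min(x$bpm[ok]), max(x$bpm[ok])))
  invisible(x)
}

#' @export
as.data.frame.hr_series <- function(x, ...) hr_to_df(x)

#' @export
plot.hr_series <- function(x, ...) {
  graphics::plot(x$times, x$bpm, type = "l", xlab = "time (s)",
                 ylab = "heart rate (BPM)",
                 main = sprintf("%s heart rate%s", x$source,
                                if (x$smoothed) " (running average)" else ""),
                 ...)
  if (any(!x$edge_mask))
    graphics::points(x$times[!x$edge_mask], x$bpm[!x$edge_mask],
                     col = "grey70", pch = 16, cex = 0.4)
  invisible(x)
}

#' @export
print.evm_hr <- function(x, ...) {
  ok <- x$hr$edge_mask
  cat("Two-pass video heart-rate estimate\n")
  cat(sprintf("  pass 1: approximation %.1f BPM on band [%g, %g]\n",
              x$pass1$hr_approx, x$pass1$band[1], x$pass1$band[2]))
  cat(sprintf("  pass 2: band [%.1f, %.1f] BPM (margin %.1f)\n",
              x$band2[1], x$band2[2], x$pass1$margin_used))
  cat(sprintf("  estimate: median %.1f BPM over %d valid samples\n",
              stats::median(x$hr$bpm[ok]), sum(ok)))
  invisible(x)
}

#' @export
summary.evm_hr <- function(object, ...) {
  ok <- object$hr$edge_mask
  out <- list(
    median_bpm = stats::median(object$hr$bpm[ok]),
    mean_bpm = mean(object$hr$bpm[ok]),
    sd_bpm = stats::sd(object$hr$bpm[ok]),
    hr_approx_pass1 = object$pass1$hr_approx,
    band_pass2 = object$band2,
    n_valid = sum(ok), n_samples = length(ok),
    n_pixels_selected = sum(object$mask))
  class(out) <- "summary.evm_hr"
  out
}

#' @export
print.summary.evm_hr <- function(x, ...) {
  cat(sprintf(
    paste0("Video HR estimate: median %.1f BPM (mean %.1f, sd %.2f)\n",
           "  pass-1 approximation %.1f BPM; pass-2 band [%.1f, %.1f]\n",
           "  %d/%d interior samples, %d pixels averaged\n"),
    x$median_bpm, x$mean_bpm, x$sd_bpm, x$hr_approx_pass1,
    x$band_pass2[1], x$band_pass2[2], x$n_valid, x$n_samples,
    x$n_pixels_selected))
  invisible(x)
}

#' @export
plot.evm_hr <- function(x, ...) {
  plot(x$hr, ...)
  graphics::lines(x$track$times, x$track$bpm, col = "grey60", lty = 3)
  graphics::abline(h = x$pass1$hr_approx, col = "grey40", lty = 2)
  invisible(x)
}

#' @export
as.data.frame.evm_hr <- function(x, ...) hr_to_df(x$hr)

#' @export
print.tf_power <- function(x, ...) {
  cat(sprintf(
    "<tf_power> %d times x %d frequencies, band [%g, %g] BPM\n",
    length(x$times), length(x$freqs_bpm),
    min(x$freqs_bpm), max(x$freqs_bpm)))
  invisible(x)
}

#' @export
plot.tf_power <- function(x, ...) {
  graphics::image(x$times, x$freqs_bpm, x$power,
                  xlab = "time (s)", ylab = "frequency (BPM)",
                  main = "wavelet power", ...)
  invisible(x)
}

#' @export
print.tf_coherence <- function(x, ...) {
  cat(sprintf(
    "<tf_coherence> %d times x %d frequencies, %.3g .. %.3g Hz\n",
    length(x$times), length(x$freqs), min(x$freqs), max(x$freqs)))
  cat(sprintf("  temporal summary (max-then-mean, interior): %.3f\n",
              temporal_coherence_summary(x)))
  invisible(x)
}

#' @export
plot.tf_coherence <- function(x, ...) {
  graphics::image(x$times, log2(x$freqs), x$coh, zlim = c(0, 1),
                  xlab = "time (s)", ylab = "log2 frequency (Hz)",
                  main = "squared wavelet coherence", ...)
  invisible(x)
}

#' @export
print.coherence_grid <- function(x, ...) {
  cat(sprintf("<coherence_grid> %d x %d cells, %d valid\n",
              x$n_rows, x$n_cols, sum(x$valid)))
  if (any(x$valid)) {
    i <- which(x$values == max(x$values, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cat(sprintf("  best cell (row %d, col %d): coherence %.3f\n",
                i[1] - 1L, i[2] - 1L, max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.coherence_grid <- function(x, ...) {
  graphics::image(seq_len(x$n_cols) - 1L, seq_len(x$n_rows) - 1L,
                  t(x$values)[, rev(seq_len(x$n_rows)), drop = FALSE],
                  zlim = c(0, 1), xlab = "grid column", ylab = "grid row",
                  main = "ROI coherence map", ...)
  invisible(x)
}

#' @export
print.aligned_response <- function(x, ...) {
  cat(sprintf(
    "<aligned_response> %d trial(s) [%s], peri window [%g, %g] s%s\n",
    x$n_trials, x$category, min(x$peri_times), max(x$peri_times),
    if (is.null(x$baseline)) ""
    else sprintf(", baseline [%g, %g] s", x$baseline[1], x$baseline[2])))
  invisible(x)
}

#' @export
plot.aligned_response <- function(x, ...) {
  sm <- summarize_response(x)
  ylim <- range(sm$mean - sm$se, sm$mean + sm$se)
  graphics::plot(sm$peri_times, sm$mean, type = "l", ylim = ylim,
                 xlab = "peristimulus time (s)",
                 ylab = "heart-rate change (BPM)",
                 main = sprintf("%s (n = %d)", x$category, x$n_trials), ...)
  graphics::polygon(c(sm$peri_times, rev(sm$peri_times)),
                    c(sm$mean + sm$se, rev(sm$mean - sm$se)),
                    col = grDevices::adjustcolor("grey50", 0.3),
                    border = NA)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s at %g Hz (t0 = %g s)\n",
              length(x$samples) / x$fs, x$fs, x$t0))
  invisible(x)
}
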