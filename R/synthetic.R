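#' Heart-rate profiles for synthetic scenarios
#'
#' Constructors for instantaneous-heart-rate functions of time (seconds ->
#' BPM) used by the generators: constant rate, linear chirp, sinusoidal
#' drift, and a step change at event onsets.
#'
#' @param bpm,from,to,center,amplitude rates in BPM.
#' @param duration_s chirp duration (reaches `to` at this time).
#' @param period_s drift period, seconds.
#' @param base_bpm,delta_bpm step baseline and jump size.
#' @param onsets event onset times, seconds.
#' @param latency_s delay from onset to the rate change.
#' @param effect_dur_s duration of the stepped rate after each onset.
#' @return a function `f(t)` returning BPM.
#' @name hr_profiles
NULL

#' @rdname hr_profiles
#' @export
hr_constant <- function(bpm) function(t) rep(bpm, length(t))

#' @rdname hr_profiles
#' @export
hr_chirp <- function(from, to, duration_s) {
  function(t) from + (to - from) * pmin(pmax(t / duration_s, 0), 1)
}

#' @rdname hr_profiles
#' @export
hr_sine <- function(center, amplitude, period_s) {
  function(t) center + amplitude * sin(2 * pi * t / period_s)
}

#' @rdname hr_profiles
#' @export
hr_step <- function(base_bpm, delta_bpm, onsets, latency_s = 1,
                    effect_dur_s = 15) {
  function(t) {
    out <- rep(base_bpm, length(t))
    for (on in onsets) {
      sel <- t >= on + latency_s & t < on + latency_s + effect_dur_s
      out[sel] <- out[sel] + delta_bpm
    }
    out
  }
}

#' @rdname hr_profiles
#' @param sd_bpm,tau_s wandering-profile fluctuation size (BPM) and
#'   correlation time (seconds).
#' @param seed RNG seed of the wandering path (the profile is a
#'   deterministic function once built).
#' @export
hr_wander <- function(base_bpm, sd_bpm = 4, tau_s = 10, duration_s = 120,
                      seed = 1) {
  grid <- seq(0, duration_s, by = 1)
  path <- with_seed(seed, {
    z <- stats::rnorm(length(grid) + 60)
    k <- exp(-0.5 * ((-30:30) / tau_s)^2)
    sm <- stats::filter(z, k / sqrt(sum(k^2)), sides = 2)
    sm[31:(30 + length(grid))]
  })
  f <- stats::approxfun(grid, base_bpm + sd_bpm * as.numeric(path),
                        rule = 2)
  function(t) f(t)
}

#' Synthetic-video scenario specification
#'
#' Describes the skin-patch recording the generator emulates: a smooth
#' reflectance texture whose in-mask pixels are modulated multiplicatively
#' at the (possibly time-varying) cardiac frequency, with sensor noise and
#' optional whole-frame integer motion jitter.
#'
#' @param duration_s clip length, seconds.
#' @param fps frame rate, frames/second.
#' @param height,width frame size in pixels.
#' @param mode `"RGB"` or `"IR"`.
#' @param hr_profile function seconds -> BPM (see [hr_profiles]); default
#'   constant 120 BPM.
#' @param modulation_amp fractional reflectance modulation amplitude
#'   (default 0.01, at the upper end of facial-skin pulsatility).
#' @param region_mask logical `H x W` matrix of pixels carrying the
#'   pulsatile signal; `NULL` = all pixels.
#' @param noise_sd per-pixel Gaussian sensor noise s.d., intensity units.
#' @param motion_jitter_px maximal whole-frame integer translation, pixels.
#' @param channel_weights RGB relative modulation weights; the default
#'   `c(0.5, 1, 0.7)` mimics the stronger green-band pulsatility. IR uses 1.
#' @param seed integer RNG seed; all output is deterministic given it.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(duration_s = 60, fps = 30, height = 64,
                          width = 64, mode = c("RGB", "IR"),
                          hr_profile = hr_constant(120),
                          modulation_amp = 0.01, region_mask = NULL,
                          noise_sd = 0.01, motion_jitter_px = 0,
                          channel_weights = c(0.5, 1, 0.7), seed = 1) {
  mode <- match.arg(mode)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (modulation_amp < 0) stop("modulation_amp must be >= 0", call. = FALSE)
  hr_test <- hr_profile(seq(0, duration_s, length.out = 16))
  if (any(hr_test <= 0) || any(hr_test >= 30 * fps))
    stop("hr_profile out of the representable (0, 30*fps) BPM range",
         call. = FALSE)
  if (!is.null(region_mask) &&
      (!is.logical(region_mask) ||
       !all(dim(region_mask) == c(height, width))))
    stop("region_mask must be a logical height x width matrix",
         call. = FALSE)
  structure(list(duration_s = duration_s, fps = fps, height = height,
                 width = width, mode = mode, hr_profile = hr_profile,
                 modulation_amp = modulation_amp, region_mask = region_mask,
                 noise_sd = noise_sd, motion_jitter_px = motion_jitter_px,
                 channel_weights = channel_weights, seed = as.integer(seed)),
            class = "scenario_spec")
}

# run `expr` under a private RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth random reflectance texture in [0.35, 0.65]
base_texture <- function(h, w) {
  tex <- matrix(stats::rnorm(h * w), h, w)
  tex3 <- array(tex, dim = c(h, w, 1))
  for (i in 1:4) tex3 <- blur_hw(tex3)
  tex <- tex3[, , 1]
  rng <- range(tex)
  if (rng[2] > rng[1]) tex <- (tex - rng[1]) / (rng[2] - rng[1])
  0.35 + 0.3 * tex
}

# cardiac phase (radians) integrated from an HR profile on a time grid
integrate_phase <- function(hr_profile, times) {
  dt <- diff(times)
  rate <- hr_profile(times) / 60          # Hz
  2 * pi * cumsum(c(0, (rate[-length(rate)] + rate[-1]) / 2 * dt))
}

shift_frame <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1), w)
  m[ri, ci]
}

#' Generate a synthetic pulsatile video clip
#'
#' A seeded smooth reflectance texture is modulated multiplicatively,
#' `base * (1 + amp * w_c * sin(phase(t)))`, on the pixels of the region
#' mask, with the cardiac phase integrated from the scenario's heart-rate
#' profile; i.i.d. Gaussian sensor noise and optional integer-pixel
#' whole-frame jitter are added on top. Deterministic given the seed.
#'
#' @param spec a [scenario_spec].
#' @return list with `clip` (a [video_clip]) and `truth` (the true
#'   instantaneous [hr_series] on the frame grid).
#' @export
synth_video <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    nt <- max(2L, round(spec$duration_s * spec$fps))
    times <- (seq_len(nt) - 1) / spec$fps
    phase <- integrate_phase(spec$hr_profile, times)
    nc <- if (spec$mode == "RGB") 3L else 1L
    wts <- if (spec$mode == "RGB") spec$channel_weights else 1
    tex <- base_texture(h, w)
    mask <- spec$region_mask
    if (is.null(mask)) mask <- matrix(TRUE, h, w)
    midx <- which(mask)
    npix <- h * w
    frames <- array(0, dim = c(h, w, nc, nt))
    s <- sin(phase)
    for (ch in seq_len(nc)) {
      M <- matrix(tex, npix, nt)
      if (length(midx))
        M[midx, ] <- tex[midx] %o% (1 + spec$modulation_amp * wts[ch] * s)
      frames[, , ch, ] <- M
    }
    if (spec$motion_jitter_px > 0) {
      j <- spec$motion_jitter_px
      dys <- sample(-j:j, nt, replace = TRUE)
      dxs <- sample(-j:j, nt, replace = TRUE)
      for (i in seq_len(nt)) {
        if (dys[i] != 0 || dxs[i] != 0)
          for (ch in seq_len(nc))
            frames[, , ch, i] <- shift_frame(frames[, , ch, i],
                                             dys[i], dxs[i])
      }
    }
    if (spec$noise_sd > 0)
      frames <- frames + array(stats::rnorm(length(frames),
                                            sd = spec$noise_sd),
                               dim = dim(frames))
    frames <- pmin(pmax(frames, 0), 1)
    clip <- video_clip(frames, times, mode = spec$mode,
                       fps_nominal = spec$fps)
    truth <- hr_series(times, spec$hr_profile(times), source = "EVM",
                       smoothed = FALSE)
    list(clip = clip, truth = truth)
  })
}

#' Generate a synthetic ECG trace with known beat times
#'
#' The cardiac phase is integrated from the heart-rate profile; a
#' stereotyped QRS-like Mexican-hat pulse (~80 ms support) is emitted at
#' every integer phase crossing, plus additive Gaussian noise.
#'
#' @param hr_profile function seconds -> BPM.
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz (>= 500).
#' @param noise_sd additive noise s.d. (QRS amplitude is 1).
#' @param seed RNG seed.
#' @return list with `ecg` (an [ecg_record]) and `peaks` (true beat times,
#'   seconds).
#' @export
synth_ecg <- function(hr_profile, duration_s, fs = 2000, noise_sd = 0,
                      seed = 1) {
  if (fs < 500) stop("fs must be >= 500 Hz", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    cycles <- integrate_phase(hr_profile, t) / (2 * pi)
    # true beat at each integer crossing of the cycle count
    kmax <- floor(cycles[n])
    peaks <- if (kmax >= 1)
      stats::approx(cycles, t, xout = seq_len(kmax), ties = "ordered")$y
    else numeric(0)
    x <- numeric(n)
    sig <- 0.012                          # ricker width -> ~80 ms support
    half <- round(0.05 * fs)
    for (tb in peaks) {
      i0 <- round(tb * fs) + 1
      lo <- max(1, i0 - half); hi <- min(n, i0 + half)
      u <- (t[lo:hi] - tb) / sig
      x[lo:hi] <- x[lo:hi] + (1 - u^2) * exp(-u^2 / 2)
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    list(ecg = ecg_record(x, fs = fs), peaks = peaks)
  })
}

#' Generate a paired synthetic session (video + ECG + events)
#'
#' Video and ECG share a single heart-rate profile; events optionally
#' inject a step change of `delta_bpm` with onset latency `latency_s`.
#'
#' @param spec a [scenario_spec]; its `hr_profile` is taken as the baseline
#'   profile when events inject a step.
#' @param onsets event onset times, seconds (`NULL` for none).
#' @param categories event labels, recycled to the onsets.
#' @param delta_bpm injected step size, BPM.
#' @param latency_s onset-to-response latency, seconds.
#' @param effect_dur_s duration of the step after each onset.
#' @param ecg_fs,ecg_noise_sd ECG sampling rate and noise.
#' @return list with `video` (video_clip), `truth` (true hr_series on the
#'   frame grid), `ecg` (ecg_record), `ecg_peaks` (true beat times),
#'   `events` (an [event_set] or `NULL`).
#' @export
synth_session <- function(spec, onsets = NULL, categories = "stimulus",
                          delta_bpm = 0, latency_s = 1, effect_dur_s = 15,
                          ecg_fs = 2000, ecg_noise_sd = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  profile <- spec$hr_profile
  if (!is.null(onsets) && delta_bpm != 0) {
    base <- profile
    step <- hr_step(0, delta_bpm, onsets, latency_s, effect_dur_s)
    profile <- function(t) base(t) + step(t) - 0  # additive step on profile
  }
  spec$hr_profile <- profile
  vid <- synth_video(spec)
  eg <- synth_ecg(profile, spec$duration_s, fs = ecg_fs,
                  noise_sd = ecg_noise_sd, seed = spec$seed + 1L)
  ev <- if (!is.null(onsets))
    event_set(onsets, rep_len(categories, length(onsets)))
  else NULL
  list(video = vid$clip, truth = vid$truth, ecg = eg$ecg,
       ecg_peaks = eg$peaks, events = ev)
}

#' Simulate a stationary heart-rate session with stimulus events
#'
#' Direct HR-series simulator for calibrating the peristimulus statistics:
#' baseline rate plus temporally smoothed Gaussian fluctuation (correlation
#' time `noise_tau_s`), with an optional per-trial post-stimulus step whose
#' size varies across trials (`delta_bpm` mean, `trial_sd` s.d.).
#'
#' @param n_trials number of events.
#' @param iti_s inter-trial interval, seconds.
#' @param delta_bpm mean injected post-stimulus step (0 = null session).
#' @param trial_sd trial-to-trial s.d. of the step, BPM.
#' @param base_bpm baseline rate.
#' @param noise_sd s.d. of the slow HR fluctuation, BPM.
#' @param noise_tau_s correlation time of the fluctuation, seconds.
#' @param fs HR sampling rate, Hz.
#' @param latency_s onset-to-step latency, seconds.
#' @param effect_dur_s step duration, seconds.
#' @param seed RNG seed.
#' @return list with `hr` (an [hr_series]), `events` (an [event_set]) and
#'   `true_delta` (per-trial injected steps).
#' @export
synth_hr_session <- function(n_trials = 30, iti_s = 34, delta_bpm = 0,
                             trial_sd = 0, base_bpm = 120, noise_sd = 2,
                             noise_tau_s = 2, fs = 10, latency_s = 1,
                             effect_dur_s = 15, seed = 1) {
  with_seed(seed, {
    lead <- 20                              # room for the first peri window
    dur <- lead + n_trials * iti_s + 20
    n <- round(dur * fs)
    t <- (seq_len(n) - 1) / fs
    noise <- stats::rnorm(n)
    k <- max(1L, round(noise_tau_s * fs))
    kern <- exp(-0.5 * ((seq_len(4 * k) - 2 * k) / k)^2)
    kern <- kern / sqrt(sum(kern^2))        # unit-variance smoothing
    sm <- stats::filter(noise, kern, sides = 2, circular = TRUE)
    bpm <- base_bpm + noise_sd * as.numeric(sm)
    onsets <- lead + (seq_len(n_trials) - 1) * iti_s
    deltas <- if (delta_bpm == 0 && trial_sd == 0) numeric(n_trials)
      else stats::rnorm(n_trials, mean = delta_bpm, sd = trial_sd)
    for (i in seq_len(n_trials)) {
      sel <- t >= onsets[i] + latency_s &
        t < onsets[i] + latency_s + effect_dur_s
      bpm[sel] <- bpm[sel] + deltas[i]
    }
    list(hr = hr_series(t, bpm, source = "EVM", smoothed = TRUE),
         events = event_set(onsets, rep("stimulus", n_trials)),
         true_delta = deltas)
  })
}
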