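# fixture builders shared across the suite; everything is generated in code

# constant-intensity clip
const_clip <- function(value = 0.5, h = 8, w = 8, nc = 1, nt = 30,
                       fps = 30) {
  mode <- if (nc == 3) "RGB" else "IR"
  video_clip(array(value, dim = c(h, w, nc, nt)), (seq_len(nt) - 1) / fps,
             mode = mode, fps_nominal = fps)
}

# clip whose every pixel carries 0.5 + amp * sin(2 pi f t)
tone_clip <- function(f_hz, amp = 0.005, h = 8, w = 8, nc = 1, nt = 300,
                      fps = 30) {
  t <- (seq_len(nt) - 1) / fps
  s <- 0.5 + amp * sin(2 * pi * f_hz * t)
  fr <- array(rep(s, each = h * w * nc), dim = c(h, w, nc, nt))
  mode <- if (nc == 3) "RGB" else "IR"
  video_clip(fr, t, mode = mode, fps_nominal = fps)
}

# peak-to-peak/2 modulation amplitude of the spatial-mean trace
clip_mod_amp <- function(clip) {
  tr <- colMeans(channel_mean_series(clip))
  (max(tr) - min(tr)) / 2
}

# smoothed HR series from a wandering profile plus tracking noise --
# a cheap stand-in for a pipeline HR estimate, used for coherence nulls
surrogate_hr <- function(seed, duration_s = 120, fps = 30, base = 120,
                         sd_bpm = 6, tau_s = 15, track_sd = 1) {
  prof <- hr_wander(base, sd_bpm, tau_s, duration_s, seed = seed)
  t <- seq(0, duration_s, by = 1 / fps)
  set.seed(seed + 10000L)
  raw <- hr_series(t, prof(t) + rnorm(length(t), sd = track_sd),
                   source = "EVM")
  running_average(raw, 20)
}
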