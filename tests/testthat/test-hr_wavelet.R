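test_that("select_pixels: full fraction, band-power oracle, tie-break", {
  clip <- const_clip(0.5, h = 6, w = 6, nt = 200)
  expect_true(all(select_pixels(clip, fraction = 1)))
  # one pixel carries an in-band tone over constant background
  fr <- array(0.5, dim = c(6, 6, 1, 200))
  t <- (0:199) / 30
  fr[4, 2, 1, ] <- 0.5 + 0.01 * sin(2 * pi * 2 * t)
  clip2 <- video_clip(fr, t, mode = "IR", fps_nominal = 30)
  m <- select_pixels(clip2, "band_power", fraction = 1 / 36)
  expect_equal(which(m), which(matrix(seq_len(36), 6, 6) ==
                                 matrix(seq_len(36), 6, 6)[4, 2]))
  # per-pixel DFT band-power oracle agrees on a noisy clip
  set.seed(5)
  fr3 <- array(runif(6 * 6 * 200, 0.4, 0.6), dim = c(6, 6, 1, 200))
  clip3 <- video_clip(fr3, t, mode = "IR", fps_nominal = 30)
  m3 <- select_pixels(clip3, "band_power", fraction = 0.25)
  f <- pmin((0:199) * 30 / 200, 30 - (0:199) * 30 / 200)
  keep <- f >= 1.5 & f <= 200 / 60
  pw <- apply(fr3[, , 1, ], c(1, 2),
              function(v) sum(Mod(fft(v))[keep]^2))
  expect_equal(sort(pw[m3], decreasing = TRUE),
               sort(pw, decreasing = TRUE)[1:sum(m3)])
  # all-tied luminosity: first pixels in (row, col) order win
  mt <- select_pixels(clip, "luminosity", fraction = 0.1)
  expect_equal(sum(mt), ceiling(0.1 * 36))
  expect_true(all(mt[1, 1:4]))   # first 4 of row 1 in row-major order
  expect_error(select_pixels(clip, fraction = 0), "fraction")
})

test_that("wavelet_power localizes tones and is linear in power", {
  fs <- 10
  t <- (0:599) / fs
  x <- sin(2 * pi * 1.8 * t)    # 108 BPM
  tf <- wavelet_power(x, fs, c(90, 200), step_bpm = 0.5)
  interior <- which(!tf$edge)
  ridges <- tf$freqs_bpm[max.col(tf$power[interior, ])]
  expect_true(all(abs(ridges - 108) <= 0.5))
  expect_true(all(tf$power >= 0))
  z <- wavelet_power(rep(0, 600), fs, c(90, 200))
  expect_true(all(z$power == 0))
})

test_that("two-tone wavelet ridges match a short-time DFT oracle", {
  fs <- 10
  t <- (0:599) / fs
  x <- sin(2 * pi * 100 / 60 * t) + sin(2 * pi * 160 / 60 * t)
  tf <- wavelet_power(x, fs, c(90, 200), step_bpm = 0.5)
  # average interior power: the tone cross-term beats cancel over time
  col <- colMeans(tf$power[!tf$edge, ])
  locmax <- which(diff(sign(diff(col))) == -2) + 1
  wav_peaks <- sort(tf$freqs_bpm[locmax[order(col[locmax],
                                              decreasing = TRUE)][1:2]])
  # STFT oracle: Hann-windowed zero-padded DFT of the central 40 s
  seg <- x[abs(t - 30) <= 20]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(seg) / (length(seg) + 1))
  sp <- Mod(fft(c(seg * w, rep(0, 4096 - length(seg)))))[1:2048]
  fbin <- (0:2047) * fs / 4096 * 60
  inband <- fbin >= 90 & fbin <= 200
  spb <- sp; spb[!inband] <- 0
  p1 <- which.max(spb)
  spb[abs(fbin - fbin[p1]) < 20] <- 0
  stft_peaks <- sort(c(fbin[p1], fbin[which.max(spb)]))
  expect_true(all(abs(wav_peaks - stft_peaks) <= 2))
})

test_that("peak_frequency_track: argmax, tie rule, chirp tracking", {
  tf <- structure(list(times = 0:4, freqs_bpm = seq(100, 140, 10),
                       power = matrix(0, 5, 5), edge = rep(FALSE, 5)),
                  class = "tf_power")
  tf$power[, 3] <- 1   # single ridge at 120
  expect_true(all(peak_frequency_track(tf)$bpm == 120))
  tf$power[2, ] <- c(0, 1, 0, 1, 0)  # equal maxima at 110 and 130 -> 110
  expect_equal(peak_frequency_track(tf)$bpm[2], 110)
  # linear chirp 100 -> 140 BPM over 60 s
  fs <- 10
  t <- (0:599) / fs
  f_inst <- (100 + 40 * t / 60) / 60
  phase <- 2 * pi * cumsum(f_inst) / fs
  tfc <- wavelet_power(sin(phase), fs, c(90, 200), step_bpm = 0.5)
  tr <- peak_frequency_track(tfc)
  ok <- tr$edge_mask
  expect_true(all(abs(tr$bpm[ok] - f_inst[ok] * 60) <= 1))
})

test_that("running_average: degenerate window, constants, direct oracle", {
  t <- (0:199) / 10
  hr <- hr_series(t, rep(c(100, 140), 100), source = "EVM")
  # window longer than the series: global mean everywhere
  g <- running_average(hr, 1000)
  expect_true(all(abs(g$bpm - 120) < 1e-9))
  expect_true(g$smoothed)
  # constant series unchanged; idempotent
  cst <- hr_series(t, rep(120, 200), source = "EVM")
  expect_equal(running_average(cst, 20)$bpm, rep(120, 200))
  # alternating 100/140 at 10 Hz, 20 s window: interior ~ 120
  sm <- running_average(hr, 20)
  interior <- t > 10 & t < 10 + 9.9
  expect_true(all(abs(sm$bpm[interior] - 120) < 1))
  # direct windowed-mean oracle on irregular values
  set.seed(6)
  vals <- 120 + rnorm(200)
  hr2 <- hr_series(t, vals, source = "EVM")
  sm2 <- running_average(hr2, 5)
  oracle <- vapply(t, function(t0)
    mean(vals[t >= t0 - 2.5 & t <= t0 + 2.5]), numeric(1))
  expect_equal(sm2$bpm, oracle)
  # monotone input stays monotone
  mono <- hr_series(t, seq(100, 140, length.out = 200), source = "EVM")
  expect_true(all(diff(running_average(mono, 8)$bpm) >= -1e-12))
})

test_that("refine_band: arithmetic, clamping, errors", {
  expect_equal(refine_band(120, 10), c(110, 130))
  expect_equal(refine_band(95, 10, c(90, 200)), c(90, 105))
  expect_equal(refine_band(195, 10, c(90, 200)), c(185, 200))
  expect_error(refine_band(5, 10), "margin")
})

test_that("estimate_hr recovers a constant rate and is channel-symmetric", {
  spec <- scenario_spec(duration_s = 30, fps = 20, height = 24, width = 24,
                        mode = "RGB", hr_profile = hr_constant(120),
                        modulation_amp = 0.01, noise_sd = 0.01, seed = 9)
  sv <- synth_video(spec)
  fit <- estimate_hr(sv$clip, params = evm_params(alpha = 50, fps = 20,
                                                  levels = 2))
  ok <- fit$hr$edge_mask
  expect_true(mean(abs(fit$hr$bpm[ok] - 120) <= 2) >= 0.95)
  expect_true(120 >= fit$band2[1] && 120 <= fit$band2[2])
  # permuting RGB channels leaves the estimate unchanged
  perm <- sv$clip
  perm$frames <- perm$frames[, , c(2, 3, 1), , drop = FALSE]
  fit2 <- estimate_hr(perm, params = evm_params(alpha = 50, fps = 20,
                                                levels = 2))
  expect_equal(fit2$hr$bpm, fit$hr$bpm)
  # too-short clip errors
  short <- crop_roi(sv$clip, roi(0, 0, 24, 24))
  short$frames <- short$frames[, , , 1:20, drop = FALSE]
  short$timestamps <- short$timestamps[1:20]
  expect_error(estimate_hr(short, params = evm_params(fps = 20)),
               "3 cycles")
})
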