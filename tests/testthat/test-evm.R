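test_that("gaussian_downsample: identity at 0 levels, constants preserved", {
  clip <- const_clip(0.3, h = 16, w = 16, nt = 5)
  expect_identical(gaussian_downsample(clip, 0), clip)
  down <- gaussian_downsample(clip, 2)
  expect_equal(dim(down$frames)[1:2], c(4, 4))
  expect_true(all(abs(down$frames - 0.3) < 1e-12))
  expect_error(gaussian_downsample(clip, 5), "too small")
})

test_that("one pyramid level equals blur-then-decimate computed directly", {
  img <- matrix(0, 8, 8); img[4, 5] <- 1   # impulse
  clip <- video_clip(array(img, dim = c(8, 8, 1, 4)), (0:3) / 30,
                     mode = "IR")
  down <- gaussian_downsample(clip, 1)
  # direct separable convolution with [1,4,6,4,1]/16, replicate padding
  k <- c(1, 4, 6, 4, 1) / 16
  pad_conv <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w) {
      acc <- 0
      for (u in -2:2) for (v in -2:2) {
        ii <- min(max(i + u, 1), h); jj <- min(max(j + v, 1), w)
        acc <- acc + k[u + 3] * k[v + 3] * m[ii, jj]
      }
      out[i, j] <- acc
    }
    out
  }
  oracle <- pad_conv(img)[seq(1, 8, 2), seq(1, 8, 2)]
  expect_equal(down$frames[, , 1, 1], oracle, tolerance = 1e-12)
})

test_that("ideal_bandpass passes in-band tones and rejects out-of-band", {
  fs <- 30
  t <- (0:599) / fs   # integer number of 2 Hz periods
  x <- sin(2 * pi * 2 * t)
  expect_lt(max(abs(ideal_bandpass(x, fs, 1.5, 3.33) - x)), 1e-10)
  expect_lt(max(abs(ideal_bandpass(sin(2 * pi * 0.2 * t), fs, 1.5, 3.33))),
            1e-10)
  expect_error(ideal_bandpass(x, fs, 0, 3), "band")
  expect_error(ideal_bandpass(x, fs, 1, 20), "band")
})

test_that("ideal_bandpass matches a direct DFT-mask oracle bin for bin", {
  fs <- 25
  n <- 250
  set.seed(4)
  x <- sin(2 * pi * 0.5 * (0:(n - 1)) / fs) +
    sin(2 * pi * 2 * (0:(n - 1)) / fs) + rnorm(n, sd = 0.1)
  y <- ideal_bandpass(x, fs, 1.5, 3)
  # independent oracle: explicit DFT, zero masked bins, inverse DFT
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  sp <- fft(x)
  sp[!(f2 >= 1.5 & f2 <= 3)] <- 0
  oracle <- Re(fft(sp, inverse = TRUE)) / n
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("magnify is the identity at alpha 0 and for constant video", {
  clip <- tone_clip(2, amp = 0.005, h = 16, w = 16, nt = 300)
  p0 <- evm_params(alpha = 0, band_bpm = c(90, 200), levels = 2, fps = 30)
  out <- magnify(clip, p0)
  expect_lt(max(abs(out$frames - clip$frames)), 1e-10)
  cc <- const_clip(0.4, h = 16, w = 16, nt = 64)
  out2 <- magnify(cc, evm_params(50, c(90, 200), 2, fps = 30))
  expect_lt(max(abs(out2$frames - 0.4)), 1e-10)
})

test_that("in-band uniform modulation scales by (1 + alpha)", {
  clip <- tone_clip(2, amp = 0.005, h = 16, w = 16, nt = 300)  # 120 BPM
  a0 <- clip_mod_amp(clip)
  for (alpha in c(1, 2, 5)) {
    out <- magnify(clip, evm_params(alpha, c(90, 200), 2, fps = 30))
    expect_equal(clip_mod_amp(out) / a0, 1 + alpha, tolerance = 0.02)
    # spatial uniformity: every pixel carries the same amplified tone
    px <- out$frames[3, 3, 1, ]
    expect_equal((max(px) - min(px)) / 2, (1 + alpha) * 0.005,
                 tolerance = 0.02)
  }
})

test_that("out-of-band modulation passes through unchanged", {
  clip <- tone_clip(0.5, amp = 0.005, h = 16, w = 16, nt = 300)  # 30 BPM
  out <- magnify(clip, evm_params(50, c(90, 200), 2, fps = 30))
  expect_lt(max(abs(out$frames - clip$frames)), 1e-6)
})

test_that("magnify preserves temporal means and commutes with offsets", {
  spec <- scenario_spec(duration_s = 5, fps = 20, height = 16, width = 16,
                        mode = "IR", hr_profile = hr_constant(120),
                        modulation_amp = 0.01, noise_sd = 0.02, seed = 8)
  clip <- synth_video(spec)$clip
  p <- evm_params(10, c(90, 200), 2, fps = 20)
  out <- magnify(clip, p)
  m_in <- apply(clip$frames, c(1, 2), mean)
  m_out <- apply(out$frames, c(1, 2), mean)
  expect_lt(max(abs(m_in - m_out)), 1e-9)
  # uniform offset commutes (before clipping)
  shifted <- clip
  shifted$frames <- clip$frames * 0.5 + 0.2
  out_sh <- magnify(shifted, p)
  expect_lt(max(abs(out_sh$frames - (0.5 * out$frames + 0.2))), 1e-9)
})

test_that("evm_params validates band, Nyquist and levels", {
  expect_error(evm_params(band_bpm = c(200, 90)), "lo < hi")
  expect_error(evm_params(band_bpm = c(90, 1000), fps = 30), "Nyquist")
  expect_error(evm_params(levels = 0), "levels")
  expect_error(evm_params(alpha = -1), "alpha")
})
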