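test_that("self-coherence is 1 everywhere after smoothing", {
  set.seed(11)
  t <- 0:179
  x <- hr_series(t, 120 + 5 * sin(2 * pi * t / 40) + rnorm(180),
                 source = "EVM")
  tfc <- wavelet_coherence(x, x)
  expect_true(all(tfc$coh >= 1 - 1e-9))
  expect_true(all(tfc$coh <= 1 + 1e-12))
})

test_that("coherence is symmetric and bounded for arbitrary inputs", {
  set.seed(12)
  t <- 0:149
  x <- hr_series(t, 110 + cumsum(rnorm(150, sd = 0.5)), source = "EVM")
  y <- hr_series(t, 130 + rnorm(150, sd = 3), source = "ECG")
  a <- wavelet_coherence(x, y)
  b <- wavelet_coherence(y, x)
  expect_equal(a$coh, b$coh)
  expect_true(all(a$coh >= 0 & a$coh <= 1))
  expect_error(wavelet_coherence(
    hr_series(0:20, rep(100, 21), source = "EVM"),
    hr_series(100:120, rep(100, 21), source = "ECG")), "overlap")
})

test_that("a shared sinusoid produces a coherence ridge at its frequency", {
  set.seed(13)
  t <- 0:239
  shared <- 6 * sin(2 * pi * t / 20)          # 0.05 Hz component
  x <- hr_series(t, 120 + shared + rnorm(240, sd = 2), source = "EVM")
  y <- hr_series(t, 100 + shared + rnorm(240, sd = 2), source = "ECG")
  tfc <- wavelet_coherence(x, y)
  interior <- tfc$valid
  coh <- tfc$coh; coh[!interior] <- NA
  at_f <- which.min(abs(tfc$freqs - 0.05))
  far <- which(tfc$freqs > 0.15)
  ridge <- mean(coh[, at_f], na.rm = TRUE)
  off <- mean(coh[, far], na.rm = TRUE)
  expect_gt(ridge, 0.9)
  expect_gt(ridge - off, 0.2)
})

test_that("independent noise stays below a Monte-Carlo surrogate null", {
  mk <- function(seed) {
    set.seed(seed)
    hr_series(0:239, 120 + rnorm(240, sd = 2), source = "EVM")
  }
  mean_interior <- function(tfc) {
    v <- tfc$coh; v[!tfc$valid] <- NA; mean(v, na.rm = TRUE)
  }
  obs <- mean_interior(wavelet_coherence(mk(100), mk(200)))
  null <- vapply(1:20, function(i)
    mean_interior(wavelet_coherence(mk(300 + i), mk(400 + i))),
    numeric(1))
  expect_lt(obs, quantile(null, 0.95) + 1e-12)
  # and far below the self-coherence ceiling
  expect_lt(obs, 0.9)
})

test_that("temporal summary: constant, single row, brute-force oracle", {
  mk_tfc <- function(coh) structure(
    list(times = seq_len(nrow(coh)) - 1, freqs = seq_len(ncol(coh)),
         coh = coh, valid = NULL), class = "tf_coherence")
  expect_equal(temporal_coherence_summary(mk_tfc(matrix(0.37, 7, 5))), 0.37)
  m <- matrix(0, 6, 4); m[, 2] <- 0.9
  expect_equal(temporal_coherence_summary(mk_tfc(m)), 0.9)
  set.seed(14)
  r <- matrix(runif(40), 8, 5)
  expect_equal(temporal_coherence_summary(mk_tfc(r)),
               mean(apply(r, 1, max)))
  expect_equal(temporal_coherence_summary(mk_tfc(r),
                                          order = "mean_of_freq_maxima"),
               mean(apply(r, 2, max)))
})

test_that("roi map localizes a quadrant-confined pulsatile signal", {
  msk <- matrix(FALSE, 40, 40); msk[21:40, 1:20] <- TRUE  # bottom-left
  prof <- hr_wander(120, 5, 12, 30, seed = 15)
  spec <- scenario_spec(duration_s = 30, fps = 20, height = 40, width = 40,
                        mode = "IR", hr_profile = prof,
                        modulation_amp = 0.01, region_mask = msk,
                        noise_sd = 0.01, seed = 16)
  ses <- synth_session(spec, ecg_noise_sd = 0.05)
  ecg_hr <- running_average(interpeak_hr(detect_r_peaks(ses$ecg)))
  grid <- roi_coherence_map(ses$video, ecg_hr, grid = c(4, 4),
                            params = evm_params(50, c(90, 200), 2,
                                                fps = 20))
  expect_equal(dim(grid$values), c(4, 4))
  expect_true(all(grid$values[grid$valid] >= 0 &
                    grid$values[grid$valid] <= 1))
  i <- which(grid$values == max(grid$values, na.rm = TRUE), arr.ind = TRUE)
  expect_true(i[1, 1] >= 3 && i[1, 2] <= 2)   # bottom-left quadrant
})

test_that("uniform pulsatile signal gives a spatially flat map", {
  prof <- hr_wander(120, 5, 12, 30, seed = 17)
  spec <- scenario_spec(duration_s = 30, fps = 20, height = 32, width = 32,
                        mode = "IR", hr_profile = prof,
                        modulation_amp = 0.01, noise_sd = 0.01, seed = 18)
  ses <- synth_session(spec, ecg_noise_sd = 0.05)
  ecg_hr <- running_average(interpeak_hr(detect_r_peaks(ses$ecg)))
  grid <- roi_coherence_map(ses$video, ecg_hr, grid = c(3, 3),
                            params = evm_params(50, c(90, 200), 2,
                                                fps = 20))
  vals <- grid$values[grid$valid]
  expect_gt(min(vals), 0.85)
  expect_lt(max(vals) - min(vals), 0.15)
})
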