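test_that("PNG frame round trip preserves intensities and timestamps", {
  spec <- scenario_spec(duration_s = 1, fps = 10, height = 12, width = 10,
                        mode = "RGB", noise_sd = 0.005, seed = 3)
  clip <- synth_video(spec)$clip
  dir <- withr::local_tempdir()
  write_video(clip, dir)
  back <- load_video(dir, mode = "RGB", fps = 10)
  # PNG quantizes to 8 bits: half a quantization step tolerance
  expect_lt(max(abs(back$frames - clip$frames)), 0.5 / 255 + 1e-9)
  expect_equal(back$timestamps, clip$timestamps, tolerance = 1e-12)
  expect_equal(dim(back$frames)[4], 10)
})

test_that("load_video maps channel modes and synthesizes timestamps", {
  dir <- withr::local_tempdir()
  for (i in 1:5)
    png::writePNG(matrix(0.5, 6, 6),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  clip <- load_video(dir, mode = "IR", fps = 30)
  expect_s3_class(clip, "video_clip")
  expect_equal(dim(clip$frames)[3], 1)
  expect_equal(clip$timestamps, (0:4) / 30)
  expect_error(load_video(file.path(dir, "nope"), "IR"), "readable")
  unlink(list.files(dir, full.names = TRUE))
  expect_error(load_video(dir, "IR"), "no frames")
})

test_that("resample_uniform picks nearest frames, earlier on ties", {
  # jittered timestamps from the nearest-assignment worked example
  fr <- array(rep(c(0.1, 0.2, 0.3, 0.4), each = 4), dim = c(2, 2, 1, 4))
  clip <- video_clip(fr, c(0, 0.03, 0.07, 0.10), mode = "IR")
  out <- resample_uniform(clip, 25)
  expect_equal(out$timestamps, c(0, 0.04, 0.08))
  expect_equal(out$frames[1, 1, 1, ], c(0.1, 0.2, 0.3))
  # brute-force nearest-index oracle on random jitter
  set.seed(1)
  ts <- cumsum(runif(40, 0.02, 0.05))
  clip2 <- video_clip(array(rep(seq_len(40) / 40, each = 4),
                            dim = c(2, 2, 1, 40)), ts, mode = "IR")
  out2 <- resample_uniform(clip2, 20)
  oracle <- vapply(out2$timestamps, function(tg) {
    d <- abs(ts - tg)
    which(d == min(d))[1]  # earlier frame on ties
  }, integer(1))
  expect_equal(out2$frames[1, 1, 1, ], seq_len(40)[oracle] / 40)
})

test_that("resample_uniform is idempotent on uniform clips", {
  clip <- const_clip(nt = 20, fps = 25)
  out <- resample_uniform(clip, 25)
  expect_equal(dim(out$frames), dim(clip$frames))
  expect_equal(out$frames, clip$frames)
  expect_equal(out$timestamps, clip$timestamps, tolerance = 1e-9)
  expect_error(resample_uniform(clip, 0), "fps_target")
})

test_that("crop_roi obeys half-open bounds, identity and composition", {
  set.seed(2)
  fr <- array(runif(48 * 64 * 1 * 3), dim = c(48, 64, 1, 3))
  clip <- video_clip(fr, (0:2) / 30, mode = "IR")
  full <- crop_roi(clip, roi(0, 0, 48, 64))
  expect_equal(full$frames, clip$frames)
  sub <- crop_roi(clip, roi(10, 5, 20, 15))
  expect_equal(dim(sub$frames)[1:2], c(10, 10))
  expect_equal(sub$frames[1, 1, 1, 1], fr[11, 6, 1, 1])
  # nested crops equal the composed crop
  a <- crop_roi(crop_roi(clip, roi(4, 8, 40, 60)), roi(2, 2, 10, 12))
  b <- crop_roi(clip, roi(6, 10, 14, 20))
  expect_equal(a$frames, b$frames)
  expect_error(crop_roi(clip, roi(0, 0, 49, 64)), "bounds")
})

test_that("channel_mean_series averages masked pixels, linearly", {
  clip <- const_clip(0.5, nc = 3, nt = 10)
  expect_true(all(channel_mean_series(clip) == 0.5))
  # single-pixel mask returns that pixel's trace
  set.seed(3)
  fr <- array(runif(4 * 4 * 1 * 6), dim = c(4, 4, 1, 6))
  clip2 <- video_clip(fr, (0:5) / 30, mode = "IR")
  m <- matrix(FALSE, 4, 4); m[2, 3] <- TRUE
  expect_equal(drop(channel_mean_series(clip2, m)), fr[2, 3, 1, ])
  # checkerboard of 0 and 1 averages to 0.5
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  clip3 <- video_clip(array(cb, dim = c(4, 4, 1, 5)), (0:4) / 30,
                      mode = "IR")
  expect_true(all(channel_mean_series(clip3) == 0.5))
  # linearity in pixel intensities
  clip4 <- video_clip(0.5 * fr + 0.1, (0:5) / 30, mode = "IR")
  expect_equal(channel_mean_series(clip4),
               0.5 * channel_mean_series(clip2) + 0.1)
  expect_error(channel_mean_series(clip2, matrix(FALSE, 4, 4)), "mask")
})
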