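test_that("sinusoid increments follow the schedule-driven phase", {
  sch <- frequency_schedule(75, amplitude = 2)
  expect_identical(sinusoid_increment(0, sch, 25), 0L)     # sin(0) = 0
  # 75 bpm = 1.25 Hz at 25 fps: frame 5 sits a quarter period in, sin = 1
  expect_identical(sinusoid_increment(5, sch, 25), 2L)
  # one full period (20 frames) sums to ~0 after rounding
  inc <- sinusoid_increments(20, sch, 25)
  expect_lte(abs(sum(inc)), 1)
  # direct evaluation oracle for a constant schedule
  n <- 0:19
  expect_identical(inc, as.integer(round(2 * sin(2 * pi * 1.25 * n / 25))))
})

test_that("phase policies agree on constant schedules and differ across segments", {
  const <- frequency_schedule(100, segment_seconds = 2)
  const_r <- frequency_schedule(100, segment_seconds = 2,
                                phase_policy = "per_segment_reset")
  expect_identical(sinusoid_increments(100, const, 25),
                   sinusoid_increments(100, const_r, 25))
  multi <- frequency_schedule(c(60, 157), segment_seconds = 1)
  multi_r <- frequency_schedule(c(60, 157), segment_seconds = 1,
                                phase_policy = "per_segment_reset")
  ic <- sinusoid_increments(75, multi, 25)
  ir <- sinusoid_increments(75, multi_r, 25)
  expect_identical(ic[1:25], ir[1:25])                     # first segment equal
  expect_false(identical(ic, ir))                          # diverge after switch
  # per-segment-reset is the literal global-time sinusoid
  n <- 0:74; t_n <- n / 25
  f <- c(60, 157)[(floor(t_n / 1) %% 2) + 1] / 60
  expect_identical(ir, as.integer(round(2 * sin(2 * pi * f * t_n))))
  # the frequency list cycles when the clip outlasts it
  expect_identical(f[51:75], rep(60 / 60, 25))
})

test_that("conceal_frame shifts only masked green values and saturates safely", {
  h <- 6; w <- 7
  fr <- array(128L, dim = c(h, w, 3))
  full <- matrix(TRUE, h, w)
  out <- conceal_frame(fr, full, 0L)
  expect_identical(unclass(out)[seq_along(fr)], as.vector(fr))  # identity
  out2 <- conceal_frame(fr, full, 2L)
  expect_true(all(out2[, , 2] == 130L))
  expect_identical(out2[, , 1], fr[, , 1])
  expect_identical(out2[, , 3], fr[, , 3])
  expect_identical(attr(out2, "clipped"), 0L)
  # saturation is counted, value pinned at 255
  sat <- fr; sat[1, 1, 2] <- 255L
  out3 <- conceal_frame(sat, full, 2L)
  expect_identical(out3[1, 1, 2], 255L)
  expect_identical(attr(out3, "clipped"), 1L)
  expect_error(conceal_frame(fr, matrix(TRUE, 3, 3), 1L), "dimensions")
})

test_that("raw and integer frame paths of conceal_frame are equivalent", {
  set.seed(7)
  for (k in 1:5) {
    fr_int <- array(sample(0:255, 6 * 7 * 3, replace = TRUE), dim = c(6, 7, 3))
    mask <- matrix(sample(c(TRUE, FALSE), 42, replace = TRUE), 6, 7)
    inc <- sample(c(-3L, -1L, 1L, 2L, 3L), 1)
    fr_raw <- as.raw(fr_int); dim(fr_raw) <- dim(fr_int)
    got_int <- conceal_frame(fr_int, mask, inc)
    got_raw <- conceal_frame(fr_raw, mask, inc)
    expect_identical(as.integer(got_raw), as.integer(as.vector(got_int)))
    expect_identical(attr(got_raw, "clipped"), attr(got_int, "clipped"))
  }
})

test_that("conceal and restore touch nothing outside the masked green plane", {
  v <- random_video(nf = 8, h = 10, w = 12, seed = 5)
  mask <- matrix(FALSE, 10, 12); mask[3:7, 4:9] <- TRUE
  sch <- frequency_schedule(100, amplitude = 2)
  cc <- conceal_video(v, sch, mask)
  for (i in seq_len(n_frames(v))) {
    a <- frame_array(v, i); b <- frame_array(cc$video, i)
    expect_identical(a[, , 1], b[, , 1])                   # red untouched
    expect_identical(a[, , 3], b[, , 3])                   # blue untouched
    expect_identical(a[, , 2][!mask], b[, , 2][!mask])     # outside mask
  }
})

test_that("restore(conceal(V)) is bit-exact over random schedules, masks, fps", {
  set.seed(99)
  for (k in 1:6) {
    fps <- sample(c(20, 25, 30), 1)
    v <- random_video(nf = sample(5:15, 1), h = 9, w = 11, fps = fps,
                      seed = k, lo = 30, hi = 220)        # headroom: no clipping
    mask <- matrix(stats::runif(99) < 0.5, 9, 11)
    sch <- frequency_schedule(sample(60:160, sample(1:4, 1), replace = TRUE),
                              segment_seconds = stats::runif(1, 0.2, 3),
                              amplitude = sample(1:4, 1),
                              phase_policy = sample(c("continuous",
                                                      "per_segment_reset"), 1))
    cc <- conceal_video(v, sch, mask)
    expect_identical(cc$clip_report$clipped_pixel_count, 0L)
    rr <- restore_video(cc$video, sch, mask)
    expect_video_identical(rr$video, v)
  }
})

test_that("restoring with the wrong frequency list does not recover the original", {
  v <- const_video(nf = 20, rgb = c(100, 128, 90))
  mask <- matrix(TRUE, 8, 10)
  cc <- conceal_video(v, frequency_schedule(100), mask)
  rr <- restore_video(cc$video, frequency_schedule(75), mask)
  expect_false(identical(video_checksum(rr$video), video_checksum(v)))
})

test_that("empty masks and no-face frames pass frames through unchanged", {
  v <- const_video(nf = 10)
  none <- matrix(FALSE, 8, 10)
  cc <- conceal_video(v, frequency_schedule(120), none)
  expect_video_identical(cc$video, v)
  # NULL-returning provider: frames skipped and logged
  prov <- function(i) if (i < 5) matrix(TRUE, 8, 10) else NULL
  cc2 <- conceal_video(v, frequency_schedule(120), prov)
  expect_identical(cc2$clip_report$skipped_frames, 5:9)
  for (i in 6:10) {
    expect_identical(cc2$video$frames[[i]], v$frames[[i]])
  }
  rr <- restore_video(cc2$video, frequency_schedule(120), prov)
  expect_video_identical(rr$video, v)
})

test_that("the injected difference signal is the rounded sinusoid at the fake rate", {
  v <- const_video(nf = 100, rgb = c(100, 128, 90), fps = 25)
  mask <- matrix(TRUE, 8, 10)
  sch <- frequency_schedule(100, amplitude = 2)
  cc <- conceal_video(v, sch, mask)
  diff_sig <- sapply(seq_len(100), function(i) {
    mean(frame_array(cc$video, i)[, , 2] - frame_array(v, i)[, , 2])
  })
  expect_equal(diff_sig, as.numeric(sinusoid_increments(100, sch, 25)))
  # dominant spectral peak of the difference sits at the schedule frequency
  expect_equal(estimate_hr(diff_sig, 25), 100, tolerance = 0.02)
})

test_that("frame-archive video I/O is bit-identical; lossy codecs are refused", {
  v <- random_video(nf = 4, h = 6, w = 7, fps = 30, seed = 3)
  dir <- tempfile("arch")
  write_video(v, dir)
  back <- read_video(dir)
  expect_video_identical(back, v)
  expect_equal(back$fps, 30)
  expect_error(write_video(v, tempfile(), codec = "mpeg4"), "lossless")
  expect_error(write_video(v, tempfile(), codec = "h264"), "lossy")
  expect_error(read_video(tempfile("nope")), "unrecognized")
})

test_that("video containers validate pixel ranges and dimensions", {
  expect_error(video_sequence(list(array(300, c(2, 2, 3))), 25), "\\[0, 255\\]")
  expect_error(video_sequence(list(array(1, c(2, 2, 2))), 25), "H x W x 3")
  expect_error(video_sequence(list(array(1, c(2, 2, 3)),
                                   array(1, c(3, 2, 3))), 25), "share")
  expect_error(video_sequence(list(array(1, c(2, 2, 3))), 0), "fps")
})
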