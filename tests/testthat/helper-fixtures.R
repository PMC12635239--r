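# shared fixtures, built in code

# constant-color video: every pixel (r, g, b), nf frames of h x w
const_video <- function(nf = 10, h = 8, w = 10, rgb = c(100, 128, 90),
                        fps = 25) {
  fr <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  video_sequence(replicate(nf, fr, simplify = FALSE), fps)
}

# deterministic pseudo-random video
random_video <- function(nf = 6, h = 8, w = 10, fps = 25, seed = 42,
                         lo = 20, hi = 235) {
  set.seed(seed)
  frames <- replicate(nf, array(sample(lo:hi, h * w * 3, replace = TRUE),
                                dim = c(h, w, 3)), simplify = FALSE)
  video_sequence(frames, fps)
}

# one cached 2048-bit key pair for tests that only need *a* key
test_keypair <- local({
  kp <- NULL
  function() {
    if (is.null(kp)) kp <<- rsa_generate_keypair(2048)
    kp
  }
})

# small synthetic clip shared across rppg/evaluation tests
small_synth <- function(duration_s = 12, noise_sd = 0.5, hr = 75,
                        pulse_amplitude = 1, seed = 11) {
  make_pulsatile_video(synth_config(
    height = 96, width = 128, fps = 25, duration_s = duration_s,
    true_hr_bpm = hr, pulse_amplitude = pulse_amplitude,
    noise_sd = noise_sd, seed = seed))
}

expect_video_identical <- function(a, b) {
  expect_identical(video_checksum(a), video_checksum(b))
}

# brute-force DTW oracle: full DP table, written independently of the
# implementation under test
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n + 1, m + 1); D[1, 1] <- 0
  for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- abs(x[i] - y[j]) +
      min(D[i, j], D[i, j + 1], D[i + 1, j])
  }
  D[n + 1, m + 1]
}
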