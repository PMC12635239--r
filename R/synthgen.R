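#' Configuration for the synthetic pulsatile-face generator
#'
#' Defaults mirror a consumer webcam recording paired with a fingertip
#' oximeter: 640 x 480 frames at 25 fps and a 60-Hz reference PPG trace.
#' The "face" is an elliptical skin patch whose green channel oscillates at
#' the true heart rate; per-pixel Gaussian sensor noise is added inside the
#' patch.
#'
#' @param height,width Frame size in pixels.
#' @param fps Frame rate.
#' @param duration_s Clip length in seconds (a warning is given below the
#'   8-s analysis-window length).
#' @param skin_rgb Base skin color (R, G, B) in \[0, 255\].
#' @param true_hr_bpm True pulse rate, 39-240 bpm.
#' @param pulse_amplitude Peak green-channel pulse amplitude (grey levels).
#' @param noise_sd Per-pixel Gaussian noise standard deviation (grey
#'   levels).
#' @param seed Integer RNG seed; generation is bit-reproducible.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(height = 480L, width = 640L, fps = 25,
                         duration_s = 10, skin_rgb = c(180, 140, 120),
                         true_hr_bpm = 75, pulse_amplitude = 1,
                         noise_sd = 2, seed = 1L) {
  stopifnot(height >= 16, width >= 16, fps > 0, duration_s > 0,
            length(skin_rgb) == 3L, all(skin_rgb >= 0 & skin_rgb <= 255),
            pulse_amplitude >= 0, noise_sd >= 0)
  if (true_hr_bpm < 39 || true_hr_bpm > 240) {
    stop("true_hr_bpm must lie in [39, 240] (the 0.65-4 Hz band)",
         call. = FALSE)
  }
  if (duration_s < 8) {
    warning("duration_s < 8 s: shorter than one analysis window")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 fps = fps, duration_s = duration_s, skin_rgb = skin_rgb,
                 true_hr_bpm = true_hr_bpm, pulse_amplitude = pulse_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# normalized canonical positions (u right, v down, unit face ellipse) for
# the semantic mesh indices used by the mask tables; remaining indices are
# laid out on a deterministic golden-angle spiral inside the ellipse.
canonical_semantic_uv <- function() {
  pts <- list(
    `10` = c(0, -0.90), `109` = c(-0.25, -0.85), `338` = c(0.25, -0.85),
    `108` = c(-0.22, -0.70), `337` = c(0.22, -0.70), `151` = c(0, -0.72),
    `107` = c(-0.20, -0.55), `336` = c(0.20, -0.55), `9` = c(0, -0.56),
    `8` = c(0, -0.44), `55` = c(-0.15, -0.45), `285` = c(0.15, -0.45),
    `116` = c(-0.62, -0.05), `123` = c(-0.60, 0.15), `147` = c(-0.50, 0.30),
    `187` = c(-0.35, 0.30), `205` = c(-0.30, 0.12), `50` = c(-0.42, -0.02),
    `345` = c(0.62, -0.05), `352` = c(0.60, 0.15), `376` = c(0.50, 0.30),
    `411` = c(0.35, 0.30), `425` = c(0.30, 0.12), `280` = c(0.42, -0.02)
  )
  ring <- function(ids, cu, cv, ru, rv) {
    th <- 2 * pi * (seq_along(ids) - 1L) / length(ids)
    for (k in seq_along(ids)) {
      pts[[as.character(ids[k])]] <<- c(cu + ru * cos(th[k]),
                                        cv + rv * sin(th[k]))
    }
  }
  ring(facemesh_regions$left_eye, -0.35, -0.30, 0.15, 0.07)
  ring(facemesh_regions$right_eye, 0.35, -0.30, 0.15, 0.07)
  ring(facemesh_regions$mouth, 0, 0.55, 0.30, 0.12)
  pts
}

#' Canonical 468-point landmark layout on an elliptical patch
#'
#' Places the mesh indices used by [facemesh_regions] at face-like
#' normalized positions (forehead bands on top, eye rings, mouth ring,
#' malar patches) and fills the remaining indices with a deterministic
#' golden-angle spiral inside the ellipse, then scales everything to the
#' patch. Deterministic: no randomness involved.
#'
#' @param center `(row, col)` of the patch center.
#' @param semi_axes `(row semi-axis, col semi-axis)` in pixels.
#' @param frame_index Frame index stored on the result.
#' @return A [landmark_set()].
#' @export
canonical_landmarks <- function(center, semi_axes, frame_index = 0L) {
  sem <- canonical_semantic_uv()
  pts <- matrix(NA_real_, 468L, 2L)
  for (nm in names(sem)) {
    uv <- sem[[nm]]
    pts[as.integer(nm) + 1L, ] <- c(center[1] + uv[2] * semi_axes[1],
                                    center[2] + uv[1] * semi_axes[2])
  }
  rest <- which(is.na(pts[, 1]))
  golden <- pi * (3 - sqrt(5))
  k <- seq_along(rest)
  r <- 0.95 * sqrt(k / length(rest))
  th <- k * golden
  pts[rest, 1] <- center[1] + r * sin(th) * semi_axes[1]
  pts[rest, 2] <- center[2] + r * cos(th) * semi_axes[2]
  landmark_set(pts, frame_index = frame_index)
}

ellipse_mask <- function(height, width, center, semi_axes) {
  rr <- matrix(0:(height - 1L), height, width)
  cc <- matrix(0:(width - 1L), height, width, byrow = TRUE)
  ((rr - center[1]) / semi_axes[1])^2 + ((cc - center[2]) / semi_axes[2])^2 <= 1
}

#' Generate a synthetic pulsatile-face video
#'
#' Renders an elliptical skin patch on a dark background. Inside the patch
#' the green channel oscillates as
#' `pulse_amplitude * sin(2*pi * true_hr_bpm/60 * t)` (spatially uniform),
#' with i.i.d. Gaussian per-pixel noise on all three channels, clipped to
#' \[0, 255\] and quantized to 8 bits. The reference PPG is the noiseless
#' unit sinusoid sampled at 60 Hz. A 468-point canonical landmark layout is
#' placed on the patch so the landmark-driven mask path can be exercised
#' end to end. Bit-reproducible for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return List with elements `video` ([video_sequence()]), `mask` (the
#'   patch mask), `landmarks` (a [landmark_set()], constant across frames),
#'   `landmark_backend` (backend function serving it for every frame),
#'   `reference_ppg` (list `value`, `fs = 60`), and `config`.
#' @export
make_pulsatile_video <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$height; w <- config$width
  center <- c((h - 1) / 2, (w - 1) / 2)
  semi <- c(0.40 * h, 0.35 * w)
  mask <- ellipse_mask(h, w, center, semi)
  idx <- which(mask)
  npx <- length(idx)
  plane <- h * w
  nf <- max(1L, as.integer(round(config$duration_s * config$fps)))

  # base frame prepared once in byte form; per frame only patch pixels change
  base <- array(as.raw(60), dim = c(h, w, 3))   # dark background
  for (ch in 1:3) base[idx + (ch - 1L) * plane] <- as.raw(config$skin_rgb[ch])

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  t_n <- (seq_len(nf) - 1L) / config$fps
  pulse <- config$pulse_amplitude * sin(2 * pi * config$true_hr_bpm / 60 * t_n)
  clamp_raw <- function(x) as.raw(pmin(255, pmax(0, round(x))))
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- base
    for (ch in 1:3) {
      v <- config$skin_rgb[ch] + if (ch == 2L) pulse[i] else 0
      v <- if (config$noise_sd > 0) {
        v + stats::rnorm(npx, sd = config$noise_sd)
      } else {
        rep(v, npx)
      }
      f[idx + (ch - 1L) * plane] <- clamp_raw(v)
    }
    frames[[i]] <- f
  }

  ppg_t <- seq(0, by = 1 / 60, length.out = max(2L, round(config$duration_s * 60)))
  lm <- canonical_landmarks(center, semi)
  list(video = video_sequence(frames, config$fps),
       mask = mask,
       landmarks = lm,
       landmark_backend = function(frame_index) list(lm),
       reference_ppg = list(value = sin(2 * pi * config$true_hr_bpm / 60 * ppg_t),
                            fs = 60),
       config = config)
}
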