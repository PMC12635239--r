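#' Spatially averaged RGB trace of a video
#'
#' For every frame, averages the R, G and B intensities over the masked
#' skin region, giving a single three-channel estimator of the pulse
#' signal. Frames whose mask is `NULL` or empty carry the previous frame's
#' value forward and are flagged.
#'
#' @param video A [video_sequence()].
#' @param masks Mask, per-frame mask list, or provider function (as in
#'   [conceal_video()]).
#' @return Object of class `rgb_trace`: list with `samples` (n x 3 matrix,
#'   columns R,G,B), `fps`, and `flagged` (0-based indices of carried
#'   frames).
#' @export
extract_rgb_trace <- function(video, masks) {
  stopifnot(inherits(video, "video_sequence"))
  provider <- as_mask_provider(masks, n_frames(video))
  nf <- n_frames(video)
  out <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("R", "G", "B")))
  flagged <- integer(0)
  plane <- video$height * video$width
  for (i in seq_len(nf)) {
    m <- provider(i - 1L)
    if (is.null(m) || !any(m)) {
      flagged <- c(flagged, i - 1L)
      if (i > 1L) out[i, ] <- out[i - 1L, ]
      next
    }
    idx <- which(m)
    f <- video$frames[[i]]
    out[i, ] <- c(mean(as.integer(f[idx])),
                  mean(as.integer(f[idx + plane])),
                  mean(as.integer(f[idx + 2L * plane])))
  }
  if (length(flagged) == nf) {
    stop("all frames have empty masks: no skin region to average",
         call. = FALSE)
  }
  # leading flagged frames (no previous value): back-fill from first valid
  first_ok <- which(!is.na(out[, 1]))[1]
  if (first_ok > 1L) out[seq_len(first_ok - 1L), ] <-
      matrix(out[first_ok, ], first_ok - 1L, 3, byrow = TRUE)
  structure(list(samples = out, fps = video$fps, flagged = flagged),
            class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat("rgb_trace: ", nrow(x$samples), " samples @ ", x$fps, " fps",
      if (length(x$flagged)) paste0(" (", length(x$flagged), " carried)"),
      "\n", sep = "")
  invisible(x)
}

#' The eight supported rPPG extraction methods
#' @format Character vector.
#' @export
RPPG_METHODS <- c("GREEN", "CHROM", "POS", "PBV", "PCA", "ICA", "LGI", "OMIT")

# power of a series inside the pulse band, used to pick components
band_power <- function(x, fs, band = c(0.65, 4)) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(0)
  x <- x - mean(x)
  nfft <- max(256L, 2^ceiling(log2(n)))
  p <- abs(stats::fft(c(x, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) 0 else sum(p[sel])
}

safe_sd_ratio <- function(a, b) {
  sb <- stats::sd(b)
  if (sb == 0) 0 else stats::sd(a) / sb
}

# normalized channels: each divided by its temporal mean
norm_channels <- function(C) {
  mu <- colMeans(C)
  mu[mu == 0] <- 1
  sweep(C, 2, mu, "/")
}

rppg_green <- function(C, fs) C[, 2]

rppg_chrom <- function(C, fs) {
  Cn <- norm_channels(C)
  Xs <- 3 * Cn[, 1] - 2 * Cn[, 2]
  Ys <- 1.5 * Cn[, 1] + Cn[, 2] - 1.5 * Cn[, 3]
  Xs - safe_sd_ratio(Xs, Ys) * Ys
}

rppg_pos <- function(C, fs) {
  n <- nrow(C)
  l <- max(2L, ceiling(1.6 * fs))
  H <- numeric(n)
  for (e in l:n) {
    s <- e - l + 1L
    Cw <- C[s:e, , drop = FALSE]
    mu <- colMeans(Cw)
    if (any(mu == 0)) next
    Cn <- sweep(Cw, 2, mu, "/")
    S1 <- Cn[, 2] - Cn[, 3]
    S2 <- Cn[, 2] + Cn[, 3] - 2 * Cn[, 1]
    h <- S1 + safe_sd_ratio(S1, S2) * S2
    H[s:e] <- H[s:e] + (h - mean(h))
  }
  H
}

rppg_pbv <- function(C, fs) {
  Cn <- norm_channels(C)
  sds <- apply(Cn, 2, stats::sd)
  if (all(sds == 0)) return(numeric(nrow(C)))
  pbv <- sds / sqrt(sum(sds^2))
  Cc <- t(scale(Cn, scale = FALSE))          # 3 x n, centered
  Q <- Cc %*% t(Cc)
  W <- tryCatch(solve(Q, pbv), error = function(e) qr.solve(Q, pbv, tol = 1e-12))
  as.numeric(t(Cc) %*% W)
}

rppg_pca <- function(C, fs) {
  if (all(apply(C, 2, stats::sd) == 0)) return(numeric(nrow(C)))
  pc <- stats::prcomp(C, center = TRUE, scale. = FALSE)
  scores <- pc$x
  pw <- apply(scores, 2, band_power, fs = fs)
  scores[, which.max(pw)]
}

# compact symmetric FastICA (logcosh), deterministic: fixed identity init
fast_ica3 <- function(X, max_iter = 200, tol = 1e-7) {
  # X: m x n, rows are mixed signals; returns unmixed components (m x n)
  m <- nrow(X)
  Xc <- X - rowMeans(X)
  V <- Xc %*% t(Xc) / ncol(Xc)
  ev <- eigen(V, symmetric = TRUE)
  d <- pmax(ev$values, 1e-12)
  K <- diag(1 / sqrt(d)) %*% t(ev$vectors)
  Z <- K %*% Xc                              # whitened
  W <- diag(m)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    # symmetric decorrelation
    s <- svd(W1)
    W1 <- s$u %*% t(s$v)
    if (max(abs(abs(diag(W1 %*% t(W))) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  W %*% Z
}

rppg_ica <- function(C, fs) {
  if (all(apply(C, 2, stats::sd) == 0)) return(numeric(nrow(C)))
  S <- fast_ica3(t(C))
  pw <- apply(S, 1, band_power, fs = fs)
  S[which.max(pw), ]
}

rppg_lgi <- function(C, fs) {
  X <- t(C)                                   # 3 x n
  sv <- svd(X)
  u1 <- sv$u[, 1]
  P <- diag(3) - tcrossprod(u1)
  (P %*% X)[2, ]
}

rppg_omit <- function(C, fs) {
  X <- t(C)                                   # 3 x n
  qd <- qr(X)
  q1 <- qr.Q(qd)[, 1]
  P <- diag(3) - tcrossprod(q1)
  (P %*% X)[2, ]
}

#' Convert an RGB trace to a pulse-candidate signal
#'
#' Eight classical rPPG projections are available. `GREEN` returns the
#' green-channel series unchanged; `CHROM` applies the chrominance
#' projection (Xs = 3R - 2G, Ys = 1.5R + G - 1.5B on temporally normalized
#' channels, alpha-tuned difference); `POS` the plane-orthogonal-to-skin
#' projection with a 1.6-s sliding window and overlap-add; `PBV` the
#' blood-volume-pulse signature weighting; `PCA`/`ICA` component
#' decompositions with the component selected by power in the 0.65-4 Hz
#' pulse band; `LGI` the local-group-invariance projection (first singular
#' vector removed); `OMIT` the orthogonal-matrix (QR) projection.
#'
#' @param trace An [extract_rgb_trace()] result, or an n x 3 RGB matrix
#'   (then `fs` must be given).
#' @param method One of `"GREEN"`, `"CHROM"`, `"POS"`, `"PBV"`, `"PCA"`,
#'   `"ICA"`, `"LGI"`, `"OMIT"`.
#' @param fs Sampling rate, only needed when `trace` is a bare matrix.
#' @return Numeric pulse-candidate vector, one sample per frame.
#' @export
rppg_extract <- function(trace, method = RPPG_METHODS, fs = NULL) {
  method <- match.arg(method)
  if (inherits(trace, "rgb_trace")) {
    C <- trace$samples
    fs <- trace$fps
  } else {
    C <- as.matrix(trace)
    if (is.null(fs)) stop("fs required when trace is a bare matrix", call. = FALSE)
  }
  if (ncol(C) != 3L) stop("trace must have three channels (R,G,B)", call. = FALSE)
  min_len <- c(GREEN = 1L, CHROM = 2L, POS = 2L, PBV = 2L, PCA = 2L,
               ICA = 4L, LGI = 2L, OMIT = 2L)[[method]]
  if (nrow(C) < min_len) {
    stop(method, " needs at least ", min_len, " samples", call. = FALSE)
  }
  fun <- switch(method,
                GREEN = rppg_green, CHROM = rppg_chrom, POS = rppg_pos,
                PBV = rppg_pbv, PCA = rppg_pca, ICA = rppg_ica,
                LGI = rppg_lgi, OMIT = rppg_omit)
  as.numeric(fun(C, fs))
}

#' Band-pass filter a pulse signal
#'
#' Zero-phase (forward-backward) Butterworth band-pass with design order 6
#' and passband 0.65-4.0 Hz (39-240 bpm), the physiological heart-rate
#' band.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed 8 Hz so the passband sits
#'   below Nyquist.
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order.
#' @return Filtered signal, same length.
#' @export
bandpass_pulse <- function(x, fs, low = 0.65, high = 4, order = 6) {
  if (fs <= 2 * high) {
    stop("sampling rate ", fs, " Hz too low for a ", high,
         " Hz passband edge", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # remove the mean first: the DC step at the signal edges otherwise excites
  # long filter transients near the low band edge on short recordings
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Split a signal into fixed-length analysis windows
#'
#' Windows of `round(window_s * fs)` samples advancing by
#' `round(stride_s * fs)` samples (8 s and 1 s by default; at 25 fps an
#' 8-s window is 200 frames).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate.
#' @param window_s,stride_s Window length and stride in seconds.
#' @return List of windows, each with attributes `start_index` (0-based
#'   sample offset) and `start_time` (seconds). Empty list (with a message)
#'   when the signal is shorter than one window.
#' @export
window_split <- function(x, fs, window_s = 8, stride_s = 1) {
  wl <- as.integer(round(window_s * fs))
  st <- max(1L, as.integer(round(stride_s * fs)))
  if (length(x) < wl) {
    message("signal shorter than one ", window_s, "-s window; no windows")
    return(list())
  }
  starts <- seq(1L, length(x) - wl + 1L, by = st)
  lapply(starts, function(s) {
    structure(x[s:(s + wl - 1L)], start_index = s - 1L,
              start_time = (s - 1L) / fs)
  })
}

#' Z-score normalization
#'
#' Centers to mean 0 and scales to unit standard deviation. A constant
#' window cannot be normalized: it is returned as zeros with attribute
#' `"degenerate" = TRUE` so callers can exclude it from signal metrics.
#'
#' @param x Numeric vector.
#' @return Normalized vector (attributes preserved).
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    out <- x * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - mean(x)) / s
  attributes(out) <- attributes(x)
  out
}

#' Estimate heart rate from a windowed pulse signal
#'
#' Computes the power spectral density of the (band-passed) window — Hann
#' taper, zero-padded FFT giving a grid finer than 1 bpm — and returns
#' 60 times the frequency of the PSD maximum within the 0.65-4.0 Hz band.
#'
#' @param x Numeric window (band-passed).
#' @param fs Sampling rate in Hz.
#' @param band Search band in Hz.
#' @return Estimated heart rate in bpm.
#' @export
estimate_hr <- function(x, fs, band = c(0.65, 4)) {
  n <- length(x)
  if (n < 8L) stop("window too short for spectral heart-rate estimation",
                   call. = FALSE)
  x <- x - mean(x)
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- x * han
  nfft <- max(8192L, 2^ceiling(log2(n)))     # <= 0.2 bpm grid at 25 Hz
  p <- abs(stats::fft(c(xw, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) == 0L || all(p[sel] == 0)) {
    stop("no spectral content in the heart-rate band", call. = FALSE)
  }
  60 * freq[sel[which.max(p[sel])]]
}

#' Resample a signal to a target rate by linear interpolation
#'
#' Used to bring the 60-Hz reference PPG onto the video frame rate before
#' window-wise comparison.
#'
#' @param x Numeric signal sampled at `fs_from`.
#' @param fs_from,fs_to Source and target sampling rates.
#' @param n_out Number of output samples (default: full duration).
#' @return Numeric vector of length `n_out`.
#' @export
resample_signal <- function(x, fs_from, fs_to,
                            n_out = floor((length(x) - 1L) * fs_to / fs_from) + 1L) {
  t_in <- (seq_along(x) - 1L) / fs_from
  t_out <- (seq_len(n_out) - 1L) / fs_to
  stats::approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}

#' Reference PPG CSV I/O
#'
#' Plain-text reference pulse traces: columns `time_s,value`, as produced
#' by a fingertip oximeter export.
#'
#' @param path CSV path.
#' @return List with `value`, `fs` (median sampling rate), `time_s`.
#' @export
read_ppg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop("PPG CSV needs columns time_s,value", call. = FALSE)
  }
  dt <- diff(d$time_s)
  list(value = d$value, fs = 1 / stats::median(dt), time_s = d$time_s)
}

#' @rdname read_ppg_csv
#' @param ppg List with `value` and `fs`.
#' @export
write_ppg_csv <- function(ppg, path) {
  utils::write.csv(
    data.frame(time_s = (seq_along(ppg$value) - 1L) / ppg$fs, value = ppg$value),
    path, row.names = FALSE)
  invisible(path)
}
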