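#' Peak signal-to-noise ratio between two videos
#'
#' Per-frame mean squared error over all pixels and channels, converted to
#' `10*log10(P_max^2 / MSE)` and averaged over frames. Frames with zero MSE
#' (bit-identical) would give infinite PSNR; they are capped at `cap`
#' (100 dB by default) to keep averages finite.
#'
#' @param original,modified [video_sequence()] objects (or single frames)
#'   of identical dimensions.
#' @param p_max Maximum possible pixel value.
#' @param cap PSNR value assigned when MSE = 0.
#' @return Mean per-frame PSNR in dB.
#' @export
video_psnr <- function(original, modified, p_max = 255, cap = 100) {
  fo <- if (inherits(original, "video_sequence")) original$frames else list(original)
  fm <- if (inherits(modified, "video_sequence")) modified$frames else list(modified)
  if (length(fo) != length(fm)) stop("frame counts differ", call. = FALSE)
  vals <- vapply(seq_along(fo), function(i) {
    a <- fo[[i]]; b <- fm[[i]]
    if (!identical(dim(a), dim(b))) stop("frame dimensions differ", call. = FALSE)
    mse <- mean((as.numeric(a) - as.numeric(b))^2)
    if (mse == 0) cap else min(cap, 10 * log10(p_max^2 / mse))
  }, numeric(1))
  mean(vals)
}

#' SSIM configuration
#'
#' Standard defaults: unit exponents, `C1 = (0.01*255)^2`,
#' `C2 = (0.03*255)^2`, `C3 = C2/2`, and an 11 x 11 Gaussian window with
#' sigma 1.5.
#'
#' @param alpha,beta,gamma Positive exponents weighting the luminance,
#'   contrast and structure terms.
#' @param dynamic_range Pixel dynamic range (P_max-like constant).
#' @param C1,C2,C3 Small positive stabilizers.
#' @param window_size,window_sigma Gaussian local window parameters.
#' @return List of class `ssim_config`.
#' @export
ssim_config <- function(alpha = 1, beta = 1, gamma = 1, dynamic_range = 255,
                        C1 = (0.01 * dynamic_range)^2,
                        C2 = (0.03 * dynamic_range)^2,
                        C3 = C2 / 2,
                        window_size = 11L, window_sigma = 1.5) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, C1 > 0, C2 > 0, C3 > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 dynamic_range = dynamic_range, C1 = C1, C2 = C2, C3 = C3,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma),
            class = "ssim_config")
}

# separable Gaussian blur with replicate padding
gauss_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

blur_1d <- function(mat, k, along_rows) {
  size <- length(k); half <- (size - 1L) %/% 2L
  if (along_rows) mat <- t(mat)
  n <- nrow(mat)
  pad <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
               mat[rep(n, half), , drop = FALSE])
  out <- matrix(0, n, ncol(mat))
  for (i in seq_len(size)) out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  if (along_rows) t(out) else out
}

gauss_blur <- function(mat, size, sigma) {
  k <- gauss_kernel(size, sigma)
  blur_1d(blur_1d(mat, k, FALSE), k, TRUE)
}

to_grey <- function(x) {
  if (length(dim(x)) == 3L) (x[, , 1] + x[, , 2] + x[, , 3]) / 3 else x
}

#' Structural similarity index between two images
#'
#' Mean of the local SSIM map, where each local window contributes the
#' product of luminance, contrast and structure comparisons
#' `l^alpha * c^beta * s^gamma` computed from Gaussian-weighted local
#' means, variances and covariance. Equals 1 for identical images and is
#' symmetric in its arguments.
#'
#' @param x,y Images: `H x W` matrices or `H x W x 3` arrays (averaged to
#'   grey), numeric on the \[0, dynamic_range\] scale.
#' @param config An [ssim_config()].
#' @return Scalar mean SSIM.
#' @export
image_ssim <- function(x, y, config = ssim_config()) {
  if (is.raw(x)) { xi <- as.integer(x); dim(xi) <- dim(x); x <- xi }
  if (is.raw(y)) { yi <- as.integer(y); dim(yi) <- dim(y); y <- yi }
  gx <- to_grey(x); gy <- to_grey(y)
  if (!identical(dim(gx), dim(gy))) stop("image dimensions differ", call. = FALSE)
  gx <- matrix(as.numeric(gx), nrow(gx)); gy <- matrix(as.numeric(gy), nrow(gy))
  w <- config$window_size; s <- config$window_sigma
  mu_x <- gauss_blur(gx, w, s); mu_y <- gauss_blur(gy, w, s)
  var_x <- pmax(gauss_blur(gx * gx, w, s) - mu_x^2, 0)
  var_y <- pmax(gauss_blur(gy * gy, w, s) - mu_y^2, 0)
  cov_xy <- gauss_blur(gx * gy, w, s) - mu_x * mu_y
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)
  l <- (2 * mu_x * mu_y + config$C1) / (mu_x^2 + mu_y^2 + config$C1)
  cc <- (2 * sd_x * sd_y + config$C2) / (var_x + var_y + config$C2)
  ss <- (cov_xy + config$C3) / (sd_x * sd_y + config$C3)
  mean(pmax(l, 0)^config$alpha * cc^config$beta * pmax(ss, 0)^config$gamma)
}

#' @rdname image_ssim
#' @param original,modified [video_sequence()] objects; per-frame SSIM is
#'   averaged over frames.
#' @export
video_ssim <- function(original, modified, config = ssim_config()) {
  stopifnot(inherits(original, "video_sequence"),
            inherits(modified, "video_sequence"))
  if (n_frames(original) != n_frames(modified)) {
    stop("frame counts differ", call. = FALSE)
  }
  mean(vapply(seq_len(n_frames(original)), function(i) {
    image_ssim(original$frames[[i]], modified$frames[[i]], config)
  }, numeric(1)))
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with absolute-difference local cost and
#' no band constraint; both end points anchored. Intended for Z-scored
#' analysis windows of the rPPG and reference PPG signals.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Cumulative alignment cost (non-negative; 0 iff the sequences
#'   align perfectly).
#' @export
dtw_distance <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("dtw_distance needs non-empty inputs", call. = FALSE)
  prev <- c(0, rep(Inf, m))
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1L)
    cost_row <- abs(x[i] - y)
    for (j in seq_len(m)) {
      cur[j + 1L] <- cost_row[j] + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Pearson correlation between two windows
#'
#' The sample correlation coefficient; reporting in the evaluation suite
#' uses its absolute value `|r|`. Zero-variance input has no defined
#' correlation: `NA` is returned with a warning so the window can be
#' excluded.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Mean absolute heart-rate error
#'
#' @param estimates,references Equal-length bpm vectors.
#' @return Mean of `|estimate - reference|` in bpm.
#' @export
delta_bpm <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(abs(estimates - references))
}

minmax_norm <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) {
    return(rep(0.5, length(v)))              # degenerate batch: neutral
  }
  (v - rng[1]) / diff(rng)
}

#' Composite overall score of concealment quality
#'
#' For a batch of evaluation records, DTW, `|r|`, PSNR and SSIM are each
#' min-max normalized across the batch and combined as
#' `OS = (DTW + (1 - r) + PSNR + SSIM) / 4`, so higher is better on every
#' axis (more signal distortion, less residual correlation, better
#' fidelity) and `0 <= OS <= 1`. The score is relative: it is defined only
#' within the batch it is normalized over. When every record ties on a
#' metric, that metric contributes the neutral value 0.5.
#'
#' @param batch Data frame with columns `dtw`, `r_abs`, `psnr`, `ssim`
#'   (one row per evaluation record).
#' @return The data frame with an added `os` column.
#' @export
overall_score <- function(batch) {
  batch <- as.data.frame(batch)
  need <- c("dtw", "r_abs", "psnr", "ssim")
  if (!all(need %in% names(batch))) {
    stop("batch needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(batch) < 1L) stop("empty batch", call. = FALSE)
  batch$os <- (minmax_norm(batch$dtw) + (1 - minmax_norm(batch$r_abs)) +
                 minmax_norm(batch$psnr) + minmax_norm(batch$ssim)) / 4
  batch
}
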