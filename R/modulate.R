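#' Video sequence container
#'
#' An ordered list of 8-bit RGB frames with a frame rate. Frames are stored
#' as `height x width x 3` raw arrays (R, G, B planes, one byte per value)
#' so a 10-s VGA clip occupies ~230 MB and frame updates touch a quarter of
#' the memory an integer representation would. Elapsed time at frame n
#' (0-based) is `t_n = n / fps`. Use [frame_array()] to obtain an integer
#' copy of a frame.
#'
#' @param frames List of `H x W x 3` arrays: raw, or numeric/integer with
#'   values in \[0, 255\] (rounded and packed to bytes).
#' @param fps Frames per second (> 0).
#' @return Object of class `video_sequence`.
#' @export
video_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a non-empty list of H x W x 3 arrays", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0", call. = FALSE)
  d <- dim(frames[[1]])
  if (length(d) != 3L || d[3] != 3L) {
    stop("each frame must be an H x W x 3 array", call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (!identical(dim(f), d)) {
      stop("all frames must share dimensions", call. = FALSE)
    }
    if (is.raw(f)) return(f)
    if (anyNA(f)) stop("pixel values must not be NA", call. = FALSE)
    r <- range(f)
    if (r[1] < 0 || r[2] > 255) {
      stop("pixel values must lie in [0, 255]", call. = FALSE)
    }
    out <- as.raw(round(f))
    dim(out) <- d
    out
  })
  structure(list(frames = frames, fps = as.numeric(fps),
                 height = d[1], width = d[2]),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat("video_sequence: ", length(x$frames), " frames, ",
      x$width, "x", x$height, " @ ", x$fps, " fps (",
      round(length(x$frames) / x$fps, 2), " s)\n", sep = "")
  invisible(x)
}

#' @rdname video_sequence
#' @param video A `video_sequence`.
#' @export
n_frames <- function(video) length(video$frames)

#' @rdname video_sequence
#' @param i Frame index, 1-based.
#' @return `frame_array` returns the i-th frame as an integer
#'   `H x W x 3` array.
#' @export
frame_array <- function(video, i) {
  f <- video$frames[[i]]
  out <- as.integer(f)
  dim(out) <- dim(f)
  out
}

#' Checksum of a video's pixel content
#'
#' SHA-256 over dimensions, frame rate and all pixel bytes; two videos have
#' equal checksums iff they are bit-identical. Used by the receiver to
#' verify exact restoration.
#'
#' @param video A `video_sequence`.
#' @return Lower-case hex string.
#' @export
video_checksum <- function(video) {
  stopifnot(inherits(video, "video_sequence"))
  hdr <- charToRaw(sprintf("pc1|%d|%d|%d|%.6f", n_frames(video),
                           video$height, video$width, video$fps))
  as.character(openssl::sha256(c(hdr, do.call(c, video$frames))))
}

# segment index (0-based, cycling) active at each elapsed time
segment_at <- function(t, schedule) {
  floor(t / schedule$segment_seconds) %% length(schedule$frequencies_bpm)
}

#' Integer sinusoid increments for a frame range
#'
#' Evaluates `round(A * sin(phi_n))` for frames `0 .. n_frames-1`, where the
#' phase follows the schedule's active fake frequency `f` (bpm): under the
#' `"continuous"` policy the phase advances by `2*pi*(f/60)/fps` each frame
#' (no discontinuity at segment boundaries); under `"per_segment_reset"` it
#' is `2*pi*(f/60)*t_n` with global elapsed time `t_n = n/fps`. When the
#' video outlasts the schedule, the frequency list cycles. The result is a
#' deterministic function of `(frame index, schedule, fps)`; concealment and
#' restoration evaluate the identical integers, which is what makes the
#' modulation exactly invertible.
#'
#' @param n_frames Number of frames.
#' @param schedule A [frequency_schedule()].
#' @param fps Frames per second.
#' @return Integer vector of length `n_frames`.
#' @export
sinusoid_increments <- function(n_frames, schedule, fps) {
  stopifnot(inherits(schedule, "frequency_schedule"), fps > 0, n_frames >= 0)
  if (n_frames == 0L) return(integer(0))
  n <- seq_len(n_frames) - 1L
  t_n <- n / fps
  f_hz <- schedule$frequencies_bpm[segment_at(t_n, schedule) + 1L] / 60
  phi <- if (schedule$phase_policy == "continuous") {
    cumsum(c(0, 2 * pi * f_hz[-n_frames] / fps))
  } else {
    2 * pi * f_hz * t_n
  }
  as.integer(round(schedule$amplitude * sin(phi)))
}

#' @rdname sinusoid_increments
#' @param frame_index Single 0-based frame index.
#' @export
sinusoid_increment <- function(frame_index, schedule, fps) {
  stopifnot(frame_index >= 0)
  sinusoid_increments(frame_index + 1L, schedule, fps)[frame_index + 1L]
}

# saturating-add lookup table: byte value b -> clamp(b + increment)
increment_lut <- function(increment) {
  as.raw(pmin(255L, pmax(0L, 0:255 + increment)))
}

# count of masked bytes that would saturate under `increment`
count_clipped <- function(bytes, increment) {
  if (increment > 0L) sum(bytes > as.raw(255L - increment))
  else if (increment < 0L) sum(bytes < as.raw(-increment))
  else 0L
}

#' Add an integer increment to the green channel inside a mask
#'
#' The green value of every masked pixel is incremented with saturating
#' arithmetic at \[0, 255\]; red and blue channels and unmasked pixels are
#' bit-identical to the input. The number of saturated (clipped) pixels is
#' attached as attribute `"clipped"` — at those pixels exact reversibility
#' is lost.
#'
#' @param frame `H x W x 3` array, raw or integer.
#' @param mask Logical `H x W` matrix (or `NULL` for pass-through).
#' @param increment Integer grey-level increment (may be negative).
#' @return The modified frame (same storage as the input) with integer
#'   attribute `"clipped"`.
#' @export
conceal_frame <- function(frame, mask, increment) {
  d <- dim(frame)
  if (is.null(mask)) return(structure(frame, clipped = 0L))
  if (!identical(dim(mask), d[1:2])) {
    stop("mask dimensions do not match frame", call. = FALSE)
  }
  increment <- as.integer(increment)
  if (increment == 0L || !any(mask)) return(structure(frame, clipped = 0L))
  idx <- which(mask) + d[1] * d[2]          # offset into the green plane
  if (is.raw(frame)) {
    b <- frame[idx]
    clipped <- count_clipped(b, increment)
    frame[idx] <- increment_lut(increment)[as.integer(b) + 1L]
  } else {
    v <- frame[idx] + increment
    clipped <- sum(v < 0L | v > 255L)
    frame[idx] <- pmin(255L, pmax(0L, v))
  }
  structure(frame, clipped = as.integer(clipped))
}

as_mask_provider <- function(masks, nf) {
  if (is.function(masks)) return(masks)
  if (is.list(masks)) {
    if (length(masks) != nf) {
      stop("need one mask per frame (got ", length(masks), " for ", nf,
           " frames)", call. = FALSE)
    }
    return(function(i) masks[[i + 1L]])
  }
  if (is.matrix(masks)) return(function(i) masks)
  stop("masks must be a matrix, a per-frame list, or a provider function",
       call. = FALSE)
}

# Frame loop shared by conceal and restore. Per-frame semantics are exactly
# conceal_frame(); the loop additionally caches the mask index vector (a
# provider typically returns the same mask object every frame) and the
# saturating-add lookup tables, which is what keeps a 10-s VGA clip below
# one second per stage.
apply_modulation <- function(video, schedule, masks, sign) {
  stopifnot(inherits(video, "video_sequence"))
  provider <- as_mask_provider(masks, n_frames(video))
  inc <- sign * sinusoid_increments(n_frames(video), schedule, video$fps)
  luts <- lapply(stats::setNames(nm = unique(inc[inc != 0L])), increment_lut)
  plane <- video$height * video$width
  clipped <- 0L
  affected <- integer(0)
  skipped <- integer(0)
  frames <- video$frames
  last_mask <- NULL
  last_idx <- NULL
  for (i in seq_along(frames)) {
    m <- provider(i - 1L)
    if (is.null(m)) { skipped <- c(skipped, i - 1L); next }
    if (inc[i] == 0L) next
    if (is.null(last_mask) || !identical(m, last_mask)) {
      if (!identical(dim(m), c(video$height, video$width))) {
        stop("mask dimensions do not match frames", call. = FALSE)
      }
      last_mask <- m
      last_idx <- which(m) + plane
    }
    if (length(last_idx) == 0L) next
    f <- frames[[i]]
    b <- f[last_idx]
    nclip <- count_clipped(b, inc[i])
    f[last_idx] <- luts[[as.character(inc[i])]][as.integer(b) + 1L]
    frames[[i]] <- f
    if (nclip > 0L) { clipped <- clipped + nclip; affected <- c(affected, i - 1L) }
  }
  out <- video
  out$frames <- frames
  list(video = out,
       clip_report = clip_report(clipped, affected, skipped))
}

clip_report <- function(clipped_pixel_count, affected_frames,
                        skipped_frames = integer(0)) {
  structure(list(clipped_pixel_count = as.integer(clipped_pixel_count),
                 affected_frames = as.integer(affected_frames),
                 skipped_frames = as.integer(skipped_frames)),
            class = "clip_report")
}

#' @export
print.clip_report <- function(x, ...) {
  cat("clip report: ", x$clipped_pixel_count, " saturated pixel(s) in ",
      length(x$affected_frames), " frame(s); ",
      length(x$skipped_frames), " frame(s) without face passed through\n",
      sep = "")
  invisible(x)
}

#' Conceal / restore the cardiac signal in a video
#'
#' `conceal_video` adds the schedule-driven integer sinusoid to the green
#' channel of every masked pixel, frame by frame; `restore_video` subtracts
#' the identical increments, so for losslessly stored video with no
#' saturation the restoration is bit-identical to the original. Frames whose
#' mask is `NULL` (no detected face) pass through unchanged on both sides.
#'
#' @param video A [video_sequence()] (must be held/stored losslessly).
#' @param schedule The [frequency_schedule()]; sender and receiver must use
#'   the same schedule, masks and fps.
#' @param masks A logical mask, a per-frame list of masks, or a provider
#'   function `function(frame_index) -> mask | NULL`.
#' @return List with elements `video` (the modified/restored
#'   `video_sequence`) and `clip_report` (saturated pixels, where exactness
#'   is lost, plus skipped no-face frames).
#' @export
conceal_video <- function(video, schedule, masks) {
  apply_modulation(video, schedule, masks, +1L)
}

#' @rdname conceal_video
#' @param modified The concealed `video_sequence`.
#' @export
restore_video <- function(modified, schedule, masks) {
  apply_modulation(modified, schedule, masks, -1L)
}

# --- lossless video I/O --------------------------------------------------

LOSSY_CODECS <- c("mpeg4", "h264", "h265", "hevc", "vp9", "av1", "mjpeg")

#' Write / read video losslessly
#'
#' Two bit-exact containers are supported. `"frames"` (default) is a
#' portable frame archive: a directory holding `meta.json` and one 8-bit
#' PNG per frame — write-then-read is bit-identical with no external
#' dependency. `"ffv1"` encodes FFV1 in Matroska through an `ffmpeg`
#' executable on the PATH and fails with a clear error when none is found.
#' Lossy codecs are refused for this path: reversible concealment requires
#' lossless storage — after a lossy transcode, traces of the modification
#' remain and the original signal cannot be recovered exactly.
#'
#' @param video A [video_sequence()].
#' @param path Destination: a directory for `"frames"`, an `.mkv` file for
#'   `"ffv1"`.
#' @param codec `"frames"` or `"ffv1"`.
#' @return `write_video` invisibly returns `path`; `read_video` returns a
#'   `video_sequence`.
#' @export
write_video <- function(video, path, codec = c("frames", "ffv1")) {
  if (length(codec) == 1L && tolower(codec) %in% LOSSY_CODECS) {
    stop("codec '", codec, "' is lossy; the reversible conceal/restore path ",
         "requires lossless storage ('frames' or 'ffv1')", call. = FALSE)
  }
  codec <- match.arg(codec)
  stopifnot(inherits(video, "video_sequence"))
  if (codec == "frames") {
    write_frame_archive(video, path)
  } else {
    write_ffv1(video, path)
  }
  invisible(path)
}

#' @rdname write_video
#' @export
read_video <- function(path) {
  if (dir.exists(path) && file.exists(file.path(path, "meta.json"))) {
    return(read_frame_archive(path))
  }
  if (grepl("\\.mkv$", path, ignore.case = TRUE)) return(read_ffv1(path))
  stop("unrecognized video container: ", path, call. = FALSE)
}

write_frame_archive <- function(video, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(format = "pulsecloak-frame-archive", version = 1L,
         fps = video$fps, n_frames = n_frames(video),
         height = video$height, width = video$width),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_len(n_frames(video))) {
    png::writePNG(frame_array(video, i) / 255,
                  file.path(path, sprintf("frame_%06d.png", i - 1L)))
  }
}

png_to_raw_frame <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  out <- as.raw(round(img[, , 1:3] * 255))
  dim(out) <- c(dim(img)[1:2], 3L)
  out
}

read_frame_archive <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  frames <- lapply(seq_len(meta$n_frames) - 1L, function(i) {
    png_to_raw_frame(file.path(path, sprintf("frame_%06d.png", i)))
  })
  video_sequence(frames, meta$fps)
}

find_ffmpeg <- function() {
  p <- Sys.which("ffmpeg")
  if (!nzchar(p)) {
    stop("no 'ffmpeg' executable on PATH: the FFV1 container is unavailable; ",
         "use codec = 'frames' (bit-exact, no external dependency)",
         call. = FALSE)
  }
  p
}

write_ffv1 <- function(video, path) {
  ffmpeg <- find_ffmpeg()
  tmp <- tempfile("ffv1frames")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_frame_archive(video, tmp)
  status <- system2(ffmpeg, c("-y", "-loglevel", "error",
                              "-framerate", format(video$fps),
                              "-start_number", "0",
                              "-i", file.path(tmp, "frame_%06d.png"),
                              "-c:v", "ffv1", "-pix_fmt", "rgb24",
                              shQuote(path)))
  if (status != 0L) stop("ffmpeg FFV1 encode failed", call. = FALSE)
}

read_ffv1 <- function(path) {
  ffmpeg <- find_ffmpeg()
  tmp <- tempfile("ffv1dec")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  status <- system2(ffmpeg, c("-y", "-loglevel", "error", "-i", shQuote(path),
                              "-start_number", "0",
                              file.path(tmp, "frame_%06d.png")))
  if (status != 0L) stop("ffmpeg FFV1 decode failed", call. = FALSE)
  files <- sort(list.files(tmp, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  info <- system2(ffmpeg, c("-i", shQuote(path)), stdout = TRUE, stderr = TRUE)
  m <- regmatches(info, regexpr("[0-9.]+ fps", info))
  fps <- if (length(m)) as.numeric(sub(" fps", "", m[[1]])) else 25
  video_sequence(lapply(files, png_to_raw_frame), fps)
}
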