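#' Facial landmark set
#'
#' Holds the 468-point face-mesh landmark coordinates for one frame.
#' Coordinates follow the package-wide convention: row-major, 0-based,
#' pixel-center units (row 0 is the top image row). Landmark indices are
#' the standard 468-point mesh topology indices, 0-based.
#'
#' @param points Numeric 468 x 2 matrix, columns `(row, col)`.
#' @param frame_index Integer frame index (0-based).
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != 468L || ncol(points) != 2L) {
    stop("a landmark set has exactly 468 (row, col) points", call. = FALSE)
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  structure(list(points = points, frame_index = as.integer(frame_index)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("468-point landmark set, frame", x$frame_index, "\n")
  invisible(x)
}

landmark_bbox_area <- function(lm) {
  p <- lm$points
  diff(range(p[, 1])) * diff(range(p[, 2]))
}

#' Read per-frame landmarks from CSV
#'
#' Expected columns: `frame_index`, `point_id` (0..467), `row`, `col`, and
#' optionally `face_id` when a frame carries more than one face.
#'
#' @param path CSV file path.
#' @return Named list: one entry per frame index (as character), each a
#'   list of `landmark_set` objects (one per face).
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame_index", "point_id", "row", "col")
  if (!all(need %in% names(d))) {
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"face_id" %in% names(d)) d$face_id <- 0L
  out <- list()
  for (fi in sort(unique(d$frame_index))) {
    df <- d[d$frame_index == fi, ]
    faces <- lapply(sort(unique(df$face_id)), function(id) {
      dff <- df[df$face_id == id, ]
      dff <- dff[order(dff$point_id), ]
      if (nrow(dff) != 468L) {
        stop("frame ", fi, " face ", id, " has ", nrow(dff),
             " points (need 468)", call. = FALSE)
      }
      landmark_set(cbind(dff$row, dff$col), frame_index = fi)
    })
    out[[as.character(fi)]] <- faces
  }
  out
}

#' @rdname read_landmarks_csv
#' @param landmarks Named list as returned by `read_landmarks_csv`, or a
#'   single `landmark_set` reused for every frame.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(`0` = list(landmarks))
  rows <- lapply(names(landmarks), function(fi) {
    do.call(rbind, lapply(seq_along(landmarks[[fi]]), function(j) {
      lm <- landmarks[[fi]][[j]]
      data.frame(frame_index = as.integer(fi), face_id = j - 1L,
                 point_id = 0:467, row = lm$points[, 1], col = lm$points[, 2])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' File-based landmark backend
#'
#' A landmark backend is a function `function(frame_index)` returning the
#' list of `landmark_set` objects detected in that frame (possibly empty).
#' This backend serves landmarks from a CSV file, so the pipeline runs
#' without any face-detection dependency; a detector-driven backend with
#' the same signature can be plugged in instead.
#'
#' @param path Landmark CSV path (see [read_landmarks_csv()]).
#' @return A backend function.
#' @export
landmark_file_backend <- function(path) {
  store <- read_landmarks_csv(path)
  function(frame_index) {
    faces <- store[[as.character(frame_index)]]
    if (is.null(faces)) list() else faces
  }
}

#' Detect the landmarks of the largest face in a frame
#'
#' Queries the pluggable backend and returns the landmark set with the
#' largest bounding-box area, or `NULL` when no face is present (such
#' frames pass through the concealment pipeline unmodified).
#'
#' @param frame_index Integer frame index (0-based).
#' @param backend A backend function, e.g. [landmark_file_backend()].
#' @return A `landmark_set` or `NULL`.
#' @export
detect_landmarks <- function(frame_index, backend) {
  if (!is.function(backend)) {
    stop("no landmark backend available; supply landmark_file_backend(csv)",
         call. = FALSE)
  }
  faces <- backend(frame_index)
  if (length(faces) == 0L) return(NULL)
  areas <- vapply(faces, landmark_bbox_area, numeric(1))
  faces[[which.max(areas)]]
}

# --- polygon rasterization ----------------------------------------------

#' Rasterize a polygon to a binary mask
#'
#' Even-odd (crossing-number) fill over pixel centers, with boundary pixels
#' included: a pixel whose center lies exactly on a polygon edge is set.
#' Vertices are `(row, col)` in the 0-based pixel-center convention.
#'
#' @param vertices Numeric k x 2 matrix of polygon vertices `(row, col)`.
#' @param dims Integer `(height, width)`.
#' @return Logical `height x width` matrix.
#' @export
rasterize_polygon <- function(vertices, dims) {
  h <- as.integer(dims[1]); w <- as.integer(dims[2])
  mask <- matrix(FALSE, h, w)
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) return(mask)
  r0 <- max(0L, floor(min(v[, 1]))); r1 <- min(h - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2]))); c1 <- min(w - 1L, ceiling(max(v[, 2])))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))         # pixel-center row coords
  px <- rep(cols, each = length(rows))          # pixel-center col coords
  inside <- rep(FALSE, length(py))
  onedge <- rep(FALSE, length(py))
  n <- nrow(v)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ay <- v[i, 1]; ax <- v[i, 2]; by <- v[j, 1]; bx <- v[j, 2]
    # crossing test on the row coordinate (half-open rule)
    crosses <- (ay <= py & py < by) | (by <= py & py < ay)
    if (any(crosses)) {
      xint <- ax + (py[crosses] - ay) * (bx - ax) / (by - ay)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint - eps
      inside <- xor(inside, hit)
    }
    # boundary: pixel center on the closed segment a-b
    dyx <- (px - ax) * (by - ay) - (py - ay) * (bx - ax)
    seg_len2 <- (bx - ax)^2 + (by - ay)^2
    if (seg_len2 > 0) {
      tpar <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / seg_len2
      onedge <- onedge |
        (abs(dyx) < eps * (1 + sqrt(seg_len2)) & tpar >= -eps & tpar <= 1 + eps)
    } else {
      onedge <- onedge | (abs(px - ax) < eps & abs(py - ay) < eps)
    }
  }
  sel <- inside | onedge
  mask[cbind(py[sel] + 1L, px[sel] + 1L)] <- TRUE
  mask
}

#' Face-mesh landmark index table for mask construction
#'
#' Index sets (0-based, standard 468-point mesh topology) defining the five
#' rPPG-rich modification regions — upper medial forehead, lower medial
#' forehead, glabella, right malar, left malar — and the eye/mouth contours
#' excluded from the whole-face skin hull. The table is an explicit package
#' constant so the convention is documented, testable and editable.
#'
#' @format Named list of integer vectors (polygon vertex indices in order).
#' @export
facemesh_regions <- list(
  upper_medial_forehead = c(10L, 109L, 108L, 151L, 337L, 338L),
  lower_medial_forehead = c(151L, 108L, 107L, 9L, 336L, 337L),
  glabella              = c(9L, 107L, 55L, 8L, 285L, 336L),
  right_malar           = c(116L, 123L, 147L, 187L, 205L, 50L),
  left_malar            = c(345L, 352L, 376L, 411L, 425L, 280L),
  left_eye  = c(33L, 7L, 163L, 144L, 145L, 153L, 154L, 155L, 133L,
                173L, 157L, 158L, 159L, 160L, 161L, 246L),
  right_eye = c(263L, 249L, 390L, 373L, 374L, 380L, 381L, 382L, 362L,
                398L, 384L, 385L, 386L, 387L, 388L, 466L),
  mouth     = c(61L, 146L, 91L, 181L, 84L, 17L, 314L, 405L, 321L, 375L,
                291L, 409L, 270L, 269L, 267L, 0L, 37L, 39L, 40L, 185L)
)

region_points <- function(lm, region) lm$points[facemesh_regions[[region]] + 1L, , drop = FALSE]

exclusion_mask <- function(lm, dims) {
  rasterize_polygon(region_points(lm, "left_eye"), dims) |
    rasterize_polygon(region_points(lm, "right_eye"), dims) |
    rasterize_polygon(region_points(lm, "mouth"), dims)
}

#' Whole-face skin mask (convex hull minus eyes and mouth)
#'
#' Rasterizes the convex hull of all 468 landmarks and removes the eye and
#' mouth polygons, giving the holistic skin patch used to average the RGB
#' signal for rPPG extraction.
#'
#' @param landmarks A `landmark_set`.
#' @param dims Integer `(height, width)` of the frame.
#' @return Logical mask matrix with attribute `region_tag = "face_hull"`.
#' @export
face_hull_mask <- function(landmarks, dims) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  hull_idx <- grDevices::chull(p[, 2], p[, 1])   # chull takes x=col, y=row
  hull <- p[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3L) {
    stop("degenerate landmarks: convex hull has no area", call. = FALSE)
  }
  m <- rasterize_polygon(hull, dims) & !exclusion_mask(landmarks, dims)
  if (!any(m)) stop("degenerate landmarks: empty face mask", call. = FALSE)
  structure(m, region_tag = "face_hull")
}

#' Five-region modification mask
#'
#' Union of the five rPPG-rich facial regions (upper/lower medial forehead,
#' glabella, right and left malar) defined by [facemesh_regions], minus the
#' eye and mouth polygons. This is the default target area for green-channel
#' modulation.
#'
#' @inheritParams face_hull_mask
#' @return Logical mask matrix with attribute `region_tag = "five_regions"`.
#' @export
five_region_mask <- function(landmarks, dims) {
  stopifnot(inherits(landmarks, "landmark_set"))
  five <- c("upper_medial_forehead", "lower_medial_forehead", "glabella",
            "right_malar", "left_malar")
  m <- matrix(FALSE, dims[1], dims[2])
  for (rg in five) m <- m | rasterize_polygon(region_points(landmarks, rg), dims)
  if (!any(m)) stop("degenerate landmarks: empty five-region mask", call. = FALSE)
  m <- m & !exclusion_mask(landmarks, dims)
  structure(m, region_tag = "five_regions")
}

#' Build a per-frame mask provider
#'
#' A mask provider is a function `function(frame_index)` returning a logical
#' frame-shaped mask, or `NULL` for frames with no detected face (those pass
#' through concealment/restoration unchanged). Providers built from the same
#' landmark source are deterministic, so sender and receiver reproduce
#' identical masks.
#'
#' @param backend Landmark backend (see [landmark_file_backend()]).
#' @param dims `(height, width)` of the frames.
#' @param region `"five_regions"` (modification) or `"face_hull"`
#'   (evaluation).
#' @return A mask provider function.
#' @export
landmark_mask_provider <- function(backend, dims,
                                   region = c("five_regions", "face_hull")) {
  region <- match.arg(region)
  fun <- if (region == "five_regions") five_region_mask else face_hull_mask
  cache <- new.env(parent = emptyenv())
  function(frame_index) {
    key <- as.character(frame_index)
    if (!is.null(cache[[key]])) return(cache[[key]])
    lm <- detect_landmarks(frame_index, backend)
    m <- if (is.null(lm)) NULL else fun(lm, dims)
    cache[[key]] <- m
    m
  }
}

#' @rdname landmark_mask_provider
#' @param mask A single logical mask reused for every frame.
#' @export
constant_mask_provider <- function(mask) {
  force(mask)
  function(frame_index) mask
}

#' Mask PNG I/O (0/255 grey PNG)
#'
#' @param mask Logical matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
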