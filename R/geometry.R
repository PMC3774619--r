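#' Polygon area by the shoelace formula
#'
#' Computes the area enclosed by a simple (non-self-intersecting) polygon.
#' The polygon is implicitly closed: the last vertex is joined to the first,
#' and the first vertex must not be repeated. The result is independent of
#' vertex orientation (clockwise or counter-clockwise).
#'
#' @param vertices A two-column numeric matrix (or coercible data frame) of
#'   vertex coordinates, one row per vertex, in order around the boundary.
#' @return The polygon area, a positive scalar in squared input units.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1)))           # 0.5
#' @seealso [polygon_centroid()]
#' @export
polygon_area <- function(vertices) {
  v <- check_vertices(vertices)
  a <- shoelace_sum(v) / 2
  if (abs(a) <= .Machine$double.eps * max(abs(v)) ^ 2 * nrow(v)) {
    stop("invalid geometry: polygon has zero area", call. = FALSE)
  }
  abs(a)
}

#' Polygon centroid (area centre of mass)
#'
#' Computes the area centroid of a simple polygon from its first moments.
#' This equals the limit of averaging the coordinates of interior pixels as
#' the pixel size shrinks to zero, which is how traced patches are usually
#' summarised in image-analysis software.
#'
#' @inheritParams polygon_area
#' @return Numeric vector `c(x, y)`.
#' @examples
#' polygon_centroid(rbind(c(0, 0), c(1, 0), c(0, 1)))  # (1/3, 1/3)
#' @export
polygon_centroid <- function(vertices) {
  v <- check_vertices(vertices)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) <= .Machine$double.eps * max(abs(v)) ^ 2 * nrow(v)) {
    stop("invalid geometry: polygon has zero area", call. = FALSE)
  }
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

shoelace_sum <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

check_vertices <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2 || anyNA(v)) {
    stop("invalid geometry: vertices must be a numeric n x 2 matrix", call. = FALSE)
  }
  if (nrow(v) < 3) {
    stop("invalid geometry: a polygon needs at least 3 vertices", call. = FALSE)
  }
  v
}

# Simplicity check by pairwise segment intersection (O(V^2); V is small for
# traced patches). Adjacent edges sharing an endpoint are skipped.
polygon_is_simple <- function(vertices) {
  v <- check_vertices(vertices)
  n <- nrow(v)
  p <- v
  q <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(p[i, ], q[i, ], p[j, ], q[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a1, a2, b1, b2) {
  d1 <- cross2(b2 - b1, a1 - b1)
  d2 <- cross2(b2 - b1, a2 - b1)
  d3 <- cross2(a2 - a1, b1 - a1)
  d4 <- cross2(a2 - a1, b2 - a1)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Construct a patch
#'
#' A patch is one traced cloth piece: a simple polygon with derived area and
#' centroid, and an optional motif-category label (used for regular quilts,
#' where patches of the same category are intended to be identical).
#'
#' @inheritParams polygon_area
#' @param category Optional character label for the patch's motif category.
#' @param check If `TRUE` (default), verify that the polygon is simple.
#' @return An object of class `"patch"`: a list with elements `vertices`
#'   (n x 2 matrix), `area`, `centroid` and `category`.
#' @export
patch <- function(vertices, category = NA_character_, check = TRUE) {
  v <- check_vertices(vertices)
  if (check && !polygon_is_simple(v)) {
    stop("invalid geometry: polygon is self-intersecting", call. = FALSE)
  }
  structure(
    list(vertices = v, area = polygon_area(v), centroid = polygon_centroid(v),
         category = as.character(category)),
    class = "patch"
  )
}

#' Construct a quilt
#'
#' A quilt is a rectangular observation window (origin at the top-left
#' corner, y axis pointing down, units cm) together with its patches.
#'
#' @param window Numeric vector `c(width, height)` in cm.
#' @param patches List of [patch()] objects.
#' @param quilt_class `"regular"` or `"crazy"`.
#' @param name Quilt name.
#' @param scale Calibration in cm per pixel that was applied at ingest
#'   (1 for data already in cm). Stored as metadata only.
#' @param validate If `TRUE` (default), enforce the quilt invariants: every
#'   vertex inside the window (tolerance 1e-9 cm) and total patched area at
#'   most the window area up to relative tolerance 1e-6.
#' @return An object of class `"quilt"`.
#' @export
quilt <- function(window, patches, quilt_class = c("crazy", "regular"),
                  name = "quilt", scale = 1, validate = TRUE) {
  quilt_class <- match.arg(quilt_class)
  stopifnot(is.numeric(window), length(window) == 2, all(window > 0))
  if (!is.list(patches) || !all(vapply(patches, inherits, logical(1), "patch"))) {
    stop("'patches' must be a list of patch objects", call. = FALSE)
  }
  if (validate) {
    tol <- 1e-9
    for (i in seq_along(patches)) {
      v <- patches[[i]]$vertices
      if (any(v[, 1] < -tol | v[, 1] > window[1] + tol |
              v[, 2] < -tol | v[, 2] > window[2] + tol)) {
        stop(sprintf("patch %d has vertices outside the window", i), call. = FALSE)
      }
    }
    total <- sum(vapply(patches, `[[`, numeric(1), "area"))
    if (total > prod(window) * (1 + 1e-6)) {
      stop("patched area exceeds the window area", call. = FALSE)
    }
  }
  structure(
    list(window = as.numeric(window), patches = patches,
         quilt_class = quilt_class, name = name, scale = scale),
    class = "quilt"
  )
}

#' @export
print.quilt <- function(x, ...) {
  cat(sprintf("<quilt '%s'> class: %s, window %.4g x %.4g cm, %d patches\n",
              x$name, x$quilt_class, x$window[1], x$window[2],
              length(x$patches)))
  invisible(x)
}

#' Patch areas of a quilt
#'
#' @param x A [quilt()].
#' @return Numeric vector of patch areas in cm^2.
#' @export
patch_areas <- function(x) {
  stopifnot(inherits(x, "quilt"))
  vapply(x$patches, `[[`, numeric(1), "area")
}

#' Patch categories of a quilt
#'
#' @param x A [quilt()].
#' @return Character vector of motif-category labels (may be `NA`).
#' @export
patch_categories <- function(x) {
  stopifnot(inherits(x, "quilt"))
  vapply(x$patches, `[[`, character(1), "category")
}

#' Patch centroids of a quilt as a point pattern
#'
#' @param x A [quilt()].
#' @return A [point_pattern()] of the patch centroids in the quilt window.
#' @export
patch_centroids <- function(x) {
  stopifnot(inherits(x, "quilt"))
  pts <- t(vapply(x$patches, `[[`, numeric(2), "centroid"))
  point_pattern(pts, x$window)
}

#' Pixel-to-cm scale calibration
#'
#' Estimates the scale (cm per pixel) twice, from the height and from the
#' width of the imaged object, and returns the average of the two estimates.
#'
#' @param pixel_height,pixel_width Image dimensions in pixels.
#' @param cm_height,cm_width True object dimensions in cm.
#' @return Scale in cm per pixel.
#' @examples
#' calibrate_scale(1000, 500, 100, 60)  # mean of 0.10 and 0.12 = 0.11
#' @export
calibrate_scale <- function(pixel_height, pixel_width, cm_height, cm_width) {
  vals <- c(pixel_height, pixel_width, cm_height, cm_width)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all calibration measurements must be positive", call. = FALSE)
  }
  (cm_height / pixel_height + cm_width / pixel_width) / 2
}

#' Crop a quilt to the bounding box of its patches
#'
#' Replaces the quilt window by the smallest axis-aligned rectangle covering
#' all patch vertices and translates all coordinates so the new window's
#' origin is (0, 0). Un-patched border strips are thereby excluded from the
#' analysis window. Idempotent.
#'
#' @param x A [quilt()] with at least one patch.
#' @return A new [quilt()] with the cropped window.
#' @export
patched_bounding_box <- function(x) {
  stopifnot(inherits(x, "quilt"))
  if (length(x$patches) == 0) stop("quilt has no patches", call. = FALSE)
  allv <- do.call(rbind, lapply(x$patches, `[[`, "vertices"))
  lo <- c(min(allv[, 1]), min(allv[, 2]))
  hi <- c(max(allv[, 1]), max(allv[, 2]))
  patches <- lapply(x$patches, function(p) {
    patch(sweep(p$vertices, 2, lo), category = p$category, check = FALSE)
  })
  quilt(window = hi - lo, patches = patches, quilt_class = x$quilt_class,
        name = x$name, scale = x$scale)
}
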