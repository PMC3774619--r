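#' Read a quilt from disk
#'
#' Two plain-text formats are supported.
#'
#' * `"json"`: a single file with fields `name`, `class`, `units` (`"cm"` or
#'   `"px"`), optional `scale_cm_per_px`, `window` (`w`, `h`) and `patches`,
#'   each patch holding `id`, optional `category`, and `vertices` as a list
#'   of `[x, y]` pairs.
#' * `"csv"`: one vertex per row with columns
#'   `quilt, patch_id, category, vertex_index, x, y`, plus a sidecar JSON
#'   file `<path>.meta.json` holding `name`, `class`, `units`,
#'   `scale_cm_per_px` and `window`.
#'
#' Files in pixel units are converted to cm at ingest using the calibration
#' scale: lengths are multiplied by the scale, so areas scale by its square.
#'
#' @param path Path to the quilt file.
#' @param format `"json"` or `"csv"`.
#' @return A [quilt()].
#' @seealso [write_quilt()]
#' @export
read_quilt <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    meta <- doc
    patch_list <- doc$patches
    get_vertices <- function(p) {
      do.call(rbind, lapply(p$vertices, function(xy) as.numeric(unlist(xy))))
    }
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("quilt", "patch_id", "category", "vertex_index", "x", "y")
    if (!all(need %in% names(tab))) {
      stop("quilt CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    meta <- jsonlite::fromJSON(paste0(path, ".meta.json"), simplifyVector = FALSE)
    ids <- unique(tab$patch_id)
    patch_list <- lapply(ids, function(id) {
      rows <- tab[tab$patch_id == id, , drop = FALSE]
      rows <- rows[order(rows$vertex_index), , drop = FALSE]
      list(id = id, category = rows$category[1],
           vertices_mat = cbind(rows$x, rows$y))
    })
    get_vertices <- function(p) p$vertices_mat
  }
  units <- if (is.null(meta$units)) "cm" else meta$units
  if (!units %in% c("cm", "px")) {
    stop("unknown units '", units, "' (expected 'cm' or 'px')", call. = FALSE)
  }
  scale <- if (units == "px") {
    if (is.null(meta$scale_cm_per_px)) {
      stop("pixel-unit quilt file lacks 'scale_cm_per_px'", call. = FALSE)
    }
    as.numeric(meta$scale_cm_per_px)
  } else 1
  window <- c(as.numeric(meta$window$w), as.numeric(meta$window$h)) * scale
  patches <- lapply(seq_along(patch_list), function(i) {
    p <- patch_list[[i]]
    v <- get_vertices(p) * scale
    id <- if (!is.null(p$id)) p$id else i
    if (is.null(dim(v)) || nrow(v) < 3) {
      stop(sprintf("patch '%s': a polygon needs at least 3 vertices", id),
           call. = FALSE)
    }
    cat_lab <- if (is.null(p$category) || is.na(p$category) || p$category == "") {
      NA_character_
    } else as.character(p$category)
    tryCatch(patch(v, category = cat_lab),
             error = function(e) {
               stop(sprintf("patch '%s': %s", id, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  quilt(window = window, patches = patches,
        quilt_class = if (is.null(meta$class)) "crazy" else meta$class,
        name = if (is.null(meta$name)) basename(path) else meta$name,
        scale = scale)
}

#' Write a quilt to disk
#'
#' Writes in cm units using the schemas documented in [read_quilt()]; a
#' write followed by a read reproduces the quilt up to floating-point
#' round-trip error.
#'
#' @param x A [quilt()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_quilt <- function(x, path, format = c("json", "csv")) {
  stopifnot(inherits(x, "quilt"))
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      name = x$name, class = x$quilt_class, units = "cm",
      window = list(w = x$window[1], h = x$window[2]),
      patches = lapply(seq_along(x$patches), function(i) {
        p <- x$patches[[i]]
        out <- list(id = i, vertices = unname(apply(p$vertices, 1, c,
                                                    simplify = FALSE)))
        if (!is.na(p$category)) out$category <- p$category
        out
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(seq_along(x$patches), function(i) {
      p <- x$patches[[i]]
      data.frame(quilt = x$name, patch_id = i,
                 category = ifelse(is.na(p$category), "", p$category),
                 vertex_index = seq_len(nrow(p$vertices)),
                 x = p$vertices[, 1], y = p$vertices[, 2])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    meta <- list(name = x$name, class = x$quilt_class, units = "cm",
                 window = list(w = x$window[1], h = x$window[2]))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' Summary records of the sixteen museum quilts
#'
#' Returns the packaged summary table for the eight regular (R1--R8) and
#' eight crazy (C1--C8) North American quilts (ca. 1870--1930) analysed in
#' the study this package reimplements: production year, patch count,
#' height, width, overall area and patched area. Only the region containing
#' patchwork counts toward the patched area. The underlying patch tracings
#' are not publicly deposited; this table supports the reproducible
#' summary arithmetic and group comparisons.
#'
#' @return A data frame with columns `name`, `quilt_class`, `year`,
#'   `n_patches`, `height_cm`, `width_cm`, `overall_area_cm2`,
#'   `patched_area_cm2`; one row per quilt.
#' @examples
#' t1 <- table1_fixture()
#' sum(t1$n_patches)  # 7135
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "museum_quilts_summary.csv",
                      package = "patchstat", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(year = "character"))
  stopifnot(nrow(tab) == 16L,
            all(tab$patched_area_cm2 <= tab$overall_area_cm2),
            all(tab$n_patches >= 1L))
  tab
}

#' Packaged motif templates for regular quilts
#'
#' Three classic block designs are shipped as JSON: `"four_patch"` (2 x 2
#' squares, two categories in a checker arrangement), `"nine_patch"`
#' (3 x 3 squares, two categories) and `"pinwheel"` (eight half-square
#' triangles in two categories). Each template tiles its block exactly.
#'
#' @param name Template name.
#' @param block_size Block side length in cm.
#' @return A `"motif_template"` object: list with `patches` (each a list
#'   with `vertices` on the unit block and `category`) and `block_size`.
#' @export
motif_template <- function(name = c("four_patch", "nine_patch", "pinwheel"),
                           block_size = 20) {
  name <- match.arg(name)
  stopifnot(block_size > 0)
  path <- system.file("extdata", "templates", paste0(name, ".json"),
                      package = "patchstat", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  patches <- lapply(doc$patches, function(p) {
    list(vertices = do.call(rbind, lapply(p$vertices, function(xy)
      as.numeric(unlist(xy)))),
      category = as.character(p$category))
  })
  areas <- vapply(patches, function(p) polygon_area(p$vertices), numeric(1))
  stopifnot(abs(sum(areas) - 1) < 1e-9)  # unit block tiles exactly
  structure(list(patches = patches, block_size = block_size, name = name),
            class = "motif_template")
}
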