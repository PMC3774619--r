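#' Generator configuration for synthetic quilts
#'
#' Bundles the tunable parameters of the synthetic-quilt generators.
#'
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param jitter_sd Standard deviation (cm) of the Gaussian "motor error"
#'   applied to seam vertices of regular quilts. The default 0.2 cm makes
#'   per-category area variation of a few percent on decimetre-scale
#'   patches, comparable to the measuring error reported for real quilts.
#' @param min_area Minimum patch area (cm^2) for crazy tessellations; the
#'   default 4 cm^2 is about the smallest piece that can be seamed.
#' @param target_n Target number of patches for crazy quilts.
#' @param method Crazy-quilt construction: `"recursive_split"` slices the
#'   window with random chords; `"voronoi_strauss"` builds the Voronoi
#'   tessellation of seeds drawn from a Strauss process.
#' @param strauss_gamma,strauss_r Strauss interaction parameters for the
#'   `"voronoi_strauss"` seeds; `strauss_r = NULL` defaults to
#'   `0.7 * sqrt(window area / target_n)`, a mild inhibition radius below
#'   the mean nearest-neighbour spacing.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, jitter_sd = 0.2, min_area = 4,
                             target_n = 300L,
                             method = c("recursive_split", "voronoi_strauss"),
                             strauss_gamma = 0.3, strauss_r = NULL) {
  method <- match.arg(method)
  stopifnot(jitter_sd >= 0, min_area > 0, target_n >= 1,
            strauss_gamma >= 0, is.null(strauss_r) || strauss_r > 0)
  structure(list(seed = as.integer(seed), jitter_sd = jitter_sd,
                 min_area = min_area, target_n = as.integer(target_n),
                 method = method, strauss_gamma = strauss_gamma,
                 strauss_r = strauss_r),
            class = "generator_config")
}

#' Build a motif template from polygons
#'
#' Constructs a regular-quilt block template from a list of polygons given
#' in unit-block coordinates; the polygons must tile the unit square
#' exactly. See [motif_template()] for the packaged classic designs.
#'
#' @param patches List of lists, each with `vertices` (n x 2 matrix in
#'   `[0, 1]^2`) and `category` (character label).
#' @param block_size Block side length in cm.
#' @param name Template name.
#' @return A `"motif_template"` object.
#' @export
new_motif_template <- function(patches, block_size = 20, name = "custom") {
  stopifnot(block_size > 0, length(patches) >= 1)
  patches <- lapply(patches, function(p) {
    list(vertices = check_vertices(p$vertices),
         category = as.character(p$category))
  })
  areas <- vapply(patches, function(p) polygon_area(p$vertices), numeric(1))
  if (abs(sum(areas) - 1) > 1e-9) {
    stop("template patches must tile the unit block exactly", call. = FALSE)
  }
  structure(list(patches = patches, block_size = block_size, name = name),
            class = "motif_template")
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a regular (block-repeat) quilt
#'
#' Tiles a motif template on a `grid_rows` x `grid_cols` translational grid
#' and perturbs the seam vertices with centred Gaussian noise of standard
#' deviation `config$jitter_sd`, emulating the unintentional motor error of
#' a human quilter. Vertices shared between adjacent patches are perturbed
#' coherently (a seam that moves carries both patches with it), vertices on
#' the window boundary move only along the boundary, and window corners are
#' fixed, so the perturbed patches still tile the window exactly.
#'
#' @param template A [motif_template()].
#' @param grid_rows,grid_cols Number of block rows/columns (>= 1).
#' @param config A [generator_config()]; uses `seed` and `jitter_sd`.
#' @return A [quilt()] with `quilt_class = "regular"`; patch categories are
#'   carried over from the template.
#' @export
generate_regular_quilt <- function(template, grid_rows, grid_cols,
                                   config = generator_config()) {
  stopifnot(inherits(template, "motif_template"),
            grid_rows >= 1, grid_cols >= 1)
  b <- template$block_size
  window <- c(grid_cols * b, grid_rows * b)
  base <- list()
  for (row in seq_len(grid_rows) - 1L) {
    for (col in seq_len(grid_cols) - 1L) {
      for (p in template$patches) {
        v <- p$vertices * b
        v[, 1] <- v[, 1] + col * b
        v[, 2] <- v[, 2] + row * b
        base[[length(base) + 1L]] <- list(vertices = v, category = p$category)
      }
    }
  }
  with_seed(config$seed, {
    patches <- jitter_tessellation(base, window, config$jitter_sd)
    quilt(window, patches, quilt_class = "regular",
          name = sprintf("synthetic-regular-%s-%dx%d-seed%d", template$name,
                         grid_rows, grid_cols, config$seed))
  })
}

# Coherent seam jitter: each distinct vertex location is displaced once and
# the displacement is shared by every polygon using it, preserving the
# tessellation. Boundary vertices are constrained to the boundary. Retries
# the whole displacement draw if any perturbed polygon degenerates.
jitter_tessellation <- function(base, window, jitter_sd, max_retry = 25L) {
  keys_of <- function(v) sprintf("%.7f_%.7f", v[, 1], v[, 2])
  all_keys <- unlist(lapply(base, function(p) keys_of(p$vertices)))
  uniq <- !duplicated(all_keys)
  coords <- do.call(rbind, lapply(base, `[[`, "vertices"))[uniq, , drop = FALSE]
  ukeys <- all_keys[uniq]
  tol <- 1e-7
  on_x <- coords[, 1] < tol | coords[, 1] > window[1] - tol
  on_y <- coords[, 2] < tol | coords[, 2] > window[2] - tol
  for (attempt in seq_len(max_retry)) {
    dx <- stats::rnorm(nrow(coords), 0, jitter_sd)
    dy <- stats::rnorm(nrow(coords), 0, jitter_sd)
    dx[on_x] <- 0
    dy[on_y] <- 0
    newx <- pmin(pmax(coords[, 1] + dx, 0), window[1])
    newy <- pmin(pmax(coords[, 2] + dy, 0), window[2])
    lookup_x <- stats::setNames(newx, ukeys)
    lookup_y <- stats::setNames(newy, ukeys)
    patches <- vector("list", length(base))
    ok <- TRUE
    for (i in seq_along(base)) {
      k <- keys_of(base[[i]]$vertices)
      v <- cbind(unname(lookup_x[k]), unname(lookup_y[k]))
      p <- tryCatch(patch(v, category = base[[i]]$category),
                    error = function(e) NULL)
      if (is.null(p)) { ok <- FALSE; break }
      patches[[i]] <- p
    }
    if (ok) return(patches)
  }
  stop("seam jitter repeatedly produced degenerate polygons; ",
       "reduce jitter_sd", call. = FALSE)
}

#' Generate a crazy (irregular) quilt
#'
#' Produces a full random tessellation of a rectangular window into
#' `config$target_n` straight-edged patches, each of area at least
#' `config$min_area`, emulating the statistical structure of crazy quilts:
#' no repeated motifs, a unimodal positively-skewed area distribution and
#' centroids compatible with an inhibitory (Strauss-like) point process.
#'
#' Two construction methods are available because the historical production
#' process is unknown and only the end product is constrained:
#' `"recursive_split"` repeatedly slices an area-weighted random patch with
#' a random chord (uniform interior point, uniform angle), skipping slices
#' that would violate the minimum area; `"voronoi_strauss"` tessellates the
#' window into the Voronoi cells of seeds drawn from a Strauss process via
#' [simulate_strauss()].
#'
#' @param window Numeric `c(width, height)` in cm.
#' @param config A [generator_config()].
#' @return A [quilt()] with `quilt_class = "crazy"`; patch areas sum to the
#'   window area (the patches tile the window).
#' @export
generate_crazy_quilt <- function(window, config = generator_config()) {
  stopifnot(is.numeric(window), length(window) == 2, all(window > 0))
  if (config$target_n * config$min_area > prod(window)) {
    stop("infeasible config: target_n * min_area exceeds the window area",
         call. = FALSE)
  }
  polys <- with_seed(config$seed, {
    switch(config$method,
           recursive_split = crazy_recursive_split(window, config),
           voronoi_strauss = crazy_voronoi_strauss(window, config))
  })
  patches <- lapply(polys, function(v) patch(v, check = FALSE))
  quilt(window, patches, quilt_class = "crazy",
        name = sprintf("synthetic-crazy-%s-n%d-seed%d", config$method,
                       config$target_n, config$seed))
}

crazy_recursive_split <- function(window, config, max_fail = 1000L) {
  polys <- list(rbind(c(0, 0), c(window[1], 0), window, c(0, window[2])))
  areas <- prod(window)
  fails <- 0L
  while (length(polys) < config$target_n) {
    i <- sample.int(length(polys), 1L, prob = areas)
    pt <- convex_interior_point(polys[[i]])
    theta <- stats::runif(1, 0, pi)
    nrm <- c(-sin(theta), cos(theta))   # chord direction (cos, sin)
    halves <- split_convex(polys[[i]], nrm, sum(nrm * pt))
    a <- vapply(halves, function(v) if (is.null(v)) 0 else abs(shoelace_sum(v)) / 2,
                numeric(1))
    if (length(halves) == 2L && all(a >= config$min_area)) {
      polys[[i]] <- halves[[1L]]
      polys[[length(polys) + 1L]] <- halves[[2L]]
      areas[i] <- a[1L]
      areas[length(polys)] <- a[2L]
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > max_fail) {
        stop("could not reach target_n: min_area rejections exhausted retries",
             call. = FALSE)
      }
    }
  }
  polys
}

# Uniform point in a convex polygon by rejection from the bounding box.
convex_interior_point <- function(v) {
  lo <- c(min(v[, 1]), min(v[, 2]))
  hi <- c(max(v[, 1]), max(v[, 2]))
  repeat {
    p <- lo + stats::runif(2) * (hi - lo)
    if (point_in_convex(v, p)) return(p)
  }
}

point_in_convex <- function(v, p) {
  n <- nrow(v)
  s <- sign(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    cross2(v[j, ] - v[i, ], p - v[i, ])
  }, numeric(1)))
  all(s >= 0) || all(s <= 0)
}

# Clip a convex polygon to the half-plane {x : n.x <= c}. Returns NULL when
# the intersection is (numerically) empty.
clip_halfplane <- function(v, nrm, cval) {
  d <- v %*% nrm - cval
  n <- nrow(v)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, v[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, v[i, ] + t * (v[j, ] - v[i, ]))
    }
  }
  if (nrow(out) < 3) return(NULL)
  # drop duplicate consecutive vertices created by clipping through a vertex
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    j <- if (i == nrow(out)) 1L else i + 1L
    if (sum((out[i, ] - out[j, ]) ^ 2) < 1e-18) keep[j] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 3) NULL else out
}

split_convex <- function(v, nrm, cval) {
  a <- clip_halfplane(v, nrm, cval)
  b <- clip_halfplane(v, -nrm, -cval)
  if (is.null(a) || is.null(b)) list(v) else list(a, b)
}

crazy_voronoi_strauss <- function(window, config, max_retry = 50L) {
  n <- config$target_n
  r <- if (is.null(config$strauss_r)) 0.7 * sqrt(prod(window) / n) else config$strauss_r
  for (attempt in seq_len(max_retry)) {
    seed_i <- sample.int(.Machine$integer.max, 1L)
    pp <- simulate_strauss(n, gamma = config$strauss_gamma, r = r,
                           window = window, seed = seed_i)
    cells <- voronoi_cells(pp$points, window)
    areas <- vapply(cells, function(v) abs(shoelace_sum(v)) / 2, numeric(1))
    if (all(areas >= config$min_area)) return(cells)
  }
  stop("voronoi_strauss: could not satisfy min_area after ", max_retry,
       " seed draws; lower min_area or target_n", call. = FALSE)
}

# Voronoi tessellation of a rectangle by successive half-plane clipping.
# For each seed, the cell starts as the window and is clipped against the
# perpendicular bisector of every other seed, nearest first; a seed further
# than twice the current maximal cell radius cannot cut the cell, so the
# scan stops early.
voronoi_cells <- function(points, window) {
  n <- nrow(points)
  rect <- rbind(c(0, 0), c(window[1], 0), window, c(0, window[2]))
  d2 <- as.matrix(stats::dist(points)) ^ 2
  lapply(seq_len(n), function(i) {
    cell <- rect
    ord <- order(d2[i, ])
    ord <- ord[ord != i]
    for (j in ord) {
      maxr2 <- max((cell[, 1] - points[i, 1]) ^ 2 + (cell[, 2] - points[i, 2]) ^ 2)
      if (d2[i, j] > 4 * maxr2) break
      nrm <- points[j, ] - points[i, ]
      cval <- sum(nrm * (points[i, ] + points[j, ]) / 2)
      cell <- clip_halfplane(cell, nrm, cval)
      if (is.null(cell)) {
        stop("degenerate Voronoi cell (coincident seeds?)", call. = FALSE)
      }
    }
    cell
  })
}
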