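# Independent oracles and fixture builders used across the suite. Oracles
# deliberately avoid the package's own code paths.

# Star-shaped simple polygon: sorted angles with random radii around a
# random centre guarantee no self-intersection.
rand_star_polygon <- function(n_vertices = 20, scale = 1) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.2, 0.5) * scale
  ctr <- stats::runif(2, 0.5, 0.6) * scale
  cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
}

# Rasterisation oracle: pixel-count area and pixel-average centroid on a
# regular grid of pitch h (even-odd crossing test, vectorised per edge).
raster_area_centroid <- function(v, h = 0.001) {
  lo <- apply(v, 2, min) - h
  hi <- apply(v, 2, max) + h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  list(area = sum(inside) * h ^ 2,
       centroid = c(mean(px[inside]), mean(py[inside])))
}

# Brute-force close-pair count (double loop).
brute_pair_count <- function(pts, r) {
  n <- nrow(pts)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((pts[i, ] - pts[j, ]) ^ 2)) <= r) s <- s + 1L
    }
  }
  s
}

# Brute-force K estimator with the same isotropic weight definition,
# computed by explicit loops and numerical arc integration for the weight.
brute_iso_weight <- function(pt, d, window, n_theta = 2048) {
  th <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  px <- pt[1] + d * cos(th)
  py <- pt[2] + d * sin(th)
  frac <- mean(px >= 0 & px <= window[1] & py >= 0 & py <= window[2])
  1 / frac
}

brute_k <- function(pts, window, r_grid, correction = "none") {
  n <- nrow(pts)
  out <- numeric(length(r_grid))
  for (g in seq_along(r_grid)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt(sum((pts[i, ] - pts[j, ]) ^ 2))
        if (d <= r_grid[g]) {
          w <- if (correction == "isotropic")
            patchstat::isotropic_weight(pts[i, ], d, window) else 1
          acc <- acc + w
        }
      }
    }
    out[g] <- prod(window) / n ^ 2 * acc
  }
  out
}

# Brute-force Strauss log pseudolikelihood with the same disk-decomposition
# integral definition, recomputed from scratch (plain loops, direct
# evaluation of each scaled sample location).
brute_logpl <- function(pts, window, beta, gamma, r, m = 32) {
  n <- nrow(pts)
  t_data <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((pts[i, ] - pts[j, ]) ^ 2)) < r) {
        t_data[i] <- t_data[i] + 1
      }
    }
  }
  if (gamma == 0 && any(t_data > 0)) return(-Inf)
  idx <- seq_len(m) - 0.5
  vr <- sqrt(idx / m)
  va <- 2 * pi * 0.6180339887498949 * seq_len(m)
  vx <- vr * cos(va); vy <- vr * sin(va)
  # per-disk Monte Carlo of (gamma^t - 1)/t, raw (unrescaled) estimate
  acc <- 0
  for (i in seq_len(n)) {
    for (s in seq_len(m)) {
      u <- pts[i, ] + r * c(vx[s], vy[s])
      if (u[1] < 0 || u[1] > window[1] || u[2] < 0 || u[2] > window[2]) next
      t_u <- 0
      for (j in seq_len(n)) {
        if (sqrt(sum((u - pts[j, ]) ^ 2)) < r) t_u <- t_u + 1
      }
      acc <- acc + (pi * r ^ 2 / m) * (gamma ^ t_u - 1) / t_u
    }
  }
  # rescale the sampled count areas so the first moment matches the exact
  # circle-rectangle overlap, as the package does
  m1 <- 0
  for (i in seq_len(n)) {
    m1 <- m1 + disk_rect_overlap(pts[i, ], r, window)
  }
  m1_mc <- 0
  ak <- numeric(0)
  for (i in seq_len(n)) {
    for (s in seq_len(m)) {
      u <- pts[i, ] + r * c(vx[s], vy[s])
      if (u[1] < 0 || u[1] > window[1] || u[2] < 0 || u[2] > window[2]) next
      t_u <- 0
      for (j in seq_len(n)) {
        if (sqrt(sum((u - pts[j, ]) ^ 2)) < r) t_u <- t_u + 1
      }
      if (t_u > length(ak)) ak <- c(ak, numeric(t_u - length(ak)))
      ak[t_u] <- ak[t_u] + (pi * r ^ 2 / m) / t_u
    }
  }
  mom <- sum(seq_along(ak) * ak)
  if (mom > 0) ak <- ak * m1 / mom
  a0 <- max(prod(window) - sum(ak), 0)
  int_val <- a0 + sum(ak * gamma ^ seq_along(ak))
  s_term <- if (gamma == 0) 0 else sum(t_data) * log(gamma)
  n * log(beta) + s_term - beta * int_val
}

# Exact |disk(centre, r) cap [0,W]x[0,H]| via quadrant decomposition with
# adaptively integrated quarter areas (independent of the package's
# closed form).
disk_rect_overlap <- function(centre, r, window) {
  quarter <- function(a, b) {
    upper <- min(a, r)
    if (upper <= 0) return(0)
    kink <- sqrt(max(r ^ 2 - min(b, r) ^ 2, 0))  # where the chord hits b
    flat <- b * min(upper, kink)
    if (upper <= kink) return(flat)
    flat + stats::integrate(function(u) sqrt(pmax(r ^ 2 - u ^ 2, 0)),
                            kink, upper, rel.tol = 1e-11,
                            subdivisions = 500L)$value
  }
  quarter(centre[1], centre[2]) +
    quarter(window[1] - centre[1], centre[2]) +
    quarter(centre[1], window[2] - centre[2]) +
    quarter(window[1] - centre[1], window[2] - centre[2])
}

# Motif template with two rectangles of distinct areas (2/3 and 1/3 of the
# block), used where category areas must differ.
two_rect_template <- function(block_size = 20) {
  new_motif_template(list(
    list(vertices = rbind(c(0, 0), c(1, 0), c(1, 2 / 3), c(0, 2 / 3)),
         category = "big"),
    list(vertices = rbind(c(0, 2 / 3), c(1, 2 / 3), c(1, 1), c(0, 1)),
         category = "small")
  ), block_size = block_size, name = "two_rect")
}

# Small crazy/regular analysis fixtures shared by pipeline and acceptance
# tests: problem sizes chosen so a full analysis runs in a few seconds.
small_crazy_report <- function(seed, target_n = 120) {
  q <- generate_crazy_quilt(c(100, 80),
                            generator_config(seed = seed, target_n = target_n))
  cfg <- quilt_config(seed = 1000 + seed, r_step = 0.05, r_max = 15)
  analyze_quilt(q, cfg)
}

small_regular_report <- function(seed, jitter_sd = 0.2) {
  tmpl <- motif_template("four_patch", block_size = 20)
  q <- generate_regular_quilt(tmpl, 4, 5,
                              generator_config(seed = seed,
                                               jitter_sd = jitter_sd))
  cfg <- quilt_config(seed = 2000 + seed, r_step = 0.05, r_max = 15)
  analyze_quilt(q, cfg)
}
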