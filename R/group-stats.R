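#' Mann-Whitney U test (asymptotic)
#'
#' Two-sample rank-sum test. `U1` counts, over all pairs, how often a value
#' of `a` is below a value of `b` (ties count 1/2); the reported `U` is
#' `min(U1, U2)`, the convention of classic statistics packages. The
#' p-value uses the normal approximation with tie-corrected variance and
#' no continuity correction (the "asymptotic significance" convention).
#'
#' @param a,b Numeric samples (each non-empty).
#' @return A `"rank_test"` object: list with `u`, `u1`, `u2`, `z`,
#'   `p_two_sided`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$u  # 0
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  rk <- rank(c(a, b))
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2          # = #{a_i > b_j} + ties/2
  u1 <- n1 * n2 - u1                    # orient as #{a_i < b_j} + ties/2
  u2 <- n1 * n2 - u1
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties ^ 3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (u1 - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(u = min(u1, u2), u1 = u1, u2 = u2, z = z,
                 p_two_sided = min(p, 1), n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), z = %.3f, p = %.4g\n",
              x$u, x$n1, x$n2, x$z, x$p_two_sided))
  invisible(x)
}

#' Cohen's d
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled`, with the
#' pooled standard deviation using the `n1 + n2 - 2` denominator. The sign
#' follows the argument order.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return Cohen's d (scalar).
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per sample", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("degenerate data: zero pooled variance", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}
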