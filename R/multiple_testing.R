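# Adaptive multiple-testing procedures: least-squares estimation of the
# number of true null hypotheses, adaptive step-down FWE (Holm), adaptive
# step-up FDR (Benjamini-Hochberg with estimated m0), Hommel adjustment, and
# conversion of adjusted p-values to standard-normal quantiles.

#' Least-squares estimate of the number of true null hypotheses
#'
#' Models the sorted p-values as a changepoint curve: with `m0` true nulls,
#' the `m - m0` smallest p-values (the alternatives) lie near zero while the
#' `m0` largest follow the uniform order-statistic line
#' `p_(m - m0 + j) = j / (m0 + 1)` (equivalently `p_(i) = 1 - (m - i) / m0`
#' in the upper tail). The estimator evaluates the total squared deviation of
#' the sorted p-values from this two-piece curve over a candidate grid of
#' `m0` values and returns the least-squares minimizer, clipped to `[0, m]`.
#'
#' @param p p-values in `(0, 1]`.
#' @param n_grid approximate number of candidate values evaluated (the exact
#'   minimizer is refined locally around the best grid point).
#' @return Estimated number of true nulls (`m0_hat`).
#' @export
estimate_m0_leastsquares <- function(p, n_grid = 200L) {
  m <- length(p)
  if (m < 2L) stop("need at least 2 p-values")
  ps <- sort(p)
  if (max(ps) - min(ps) < .Machine$double.eps) {
    warning("degenerate (constant) p-values: returning m0 = m")
    return(m)
  }
  sse <- function(k) {
    low <- if (k < m) sum(ps[seq_len(m - k)]^2) else 0
    if (k == 0L) return(low)
    j <- seq_len(k)
    low + sum((ps[m - k + j] - j / (k + 1))^2)
  }
  cand <- unique(c(0L, round(seq(1, m, length.out = min(n_grid, m)))))
  vals <- vapply(cand, sse, 1)
  best <- cand[which.min(vals)]
  # local refinement around the best grid point
  step <- max(1L, ceiling(m / n_grid))
  local <- max(0L, best - step):min(m, best + step)
  local_vals <- vapply(local, sse, 1)
  local[which.min(local_vals)]
}

#' Adaptive step-down (Holm) FWE-adjusted p-values
#'
#' Classical Holm with the multiplier `m - j + 1` replaced by
#' `max(m0_hat - j + 1, 1)`: sorting p ascending,
#' `adj_(i) = max_{j <= i} min(1, max(m0_hat - j + 1, 1) * p_(j))`, restored
#' to the input order. With `m0_hat = m` this is exactly Holm's step-down
#' method.
#'
#' @param p p-values.
#' @param m0_hat estimated number of true nulls in `[0, m]` (default `m`).
#' @return Adjusted p-values (monotone, bounded by 1).
#' @export
holm_adaptive <- function(p, m0_hat = length(p)) {
  m <- length(p)
  if (m0_hat < 0 || m0_hat > m) stop("m0_hat must lie in [0, m]")
  o <- order(p)
  ps <- p[o]
  mult <- pmax(m0_hat - seq_len(m) + 1, 1)
  adj <- cummax(pmin(mult * ps, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Adaptive step-up (Benjamini-Hochberg) FDR-adjusted p-values
#'
#' BH step-up with `m` replaced by the estimated true-null count:
#' `adj_(i) = min_{j >= i} min(1, m0_hat * p_(j) / j)`. With `m0_hat = m`
#' this is exactly the classical BH adjustment.
#'
#' @param p p-values.
#' @param m0_hat estimated number of true nulls in `(0, m]` (default `m`).
#' @return Adjusted p-values.
#' @export
fdr_adaptive_stepup <- function(p, m0_hat = length(p)) {
  m <- length(p)
  if (m0_hat <= 0 || m0_hat > m) stop("m0_hat must lie in (0, m]")
  o <- order(p, decreasing = TRUE)
  ps <- p[o]
  i <- m:1L  # ranks of the descending-sorted values
  adj <- cummin(pmin(m0_hat * ps / i, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Hommel-adjusted p-values
#'
#' Hommel's (1988) closed-testing adjustment, computed with Wright's (1992)
#' algorithm. More powerful than Holm, valid under the same positive-
#' dependence conditions as Simes' test.
#'
#' @param p p-values.
#' @return Adjusted p-values.
#' @export
hommel_adjust <- function(p) {
  n <- length(p)
  if (n == 1L) return(p)
  o <- order(p)
  a <- p[o]
  q <- rep(min(n * a / seq_len(n)), n)
  pa <- q
  for (m in if (n > 2L) (n - 1L):2L else integer(0)) {
    i1 <- seq_len(n - m + 1L)
    i2 <- (n - m + 2L):n
    q1 <- min(m * a[i2] / (2:m))
    q[i1] <- pmin(m * a[i1], q1)
    q[i2] <- q[n - m + 1L]
    pa <- pmax(pa, q)
  }
  adj <- pmax(pa, a)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Convert adjusted p-values to standard-normal quantiles
#'
#' `z = qnorm(1 - p)`; `p = 1` would map to `-Inf`, so z is floored at the
#' quantile equivalent to `p = 1 - 1e-16` (about -8.2) to keep maps finite.
#'
#' @param p_adjusted p-values in `(0, 1]`.
#' @return Z-values, monotone decreasing in p.
#' @export
p_to_z <- function(p_adjusted) {
  if (any(p_adjusted <= 0, na.rm = TRUE)) stop("p-values must be > 0")
  z <- stats::qnorm(p_adjusted, lower.tail = FALSE)
  pmax(z, stats::qnorm(1e-16))
}
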