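#' Occupancy moments
#'
#' First and second moments of the solvent occupancy distribution of an
#' observation volume.
#'
#' @param n_mean `<n>` (>= 0).
#' @param n2_mean `<n^2>` (>= n_mean^2).
#' @return Object of class `occupancy_moments`.
#' @export
occupancy_moments <- function(n_mean, n2_mean) {
  if (!is.finite(n_mean) || n_mean < 0)
    stop("occupancy_moments: n_mean must be >= 0")
  if (!is.finite(n2_mean) || n2_mean < n_mean^2 * (1 - 1e-12))
    stop("occupancy_moments: n2_mean implies negative variance")
  structure(list(n_mean = n_mean, n2_mean = n2_mean,
                 variance = n2_mean - n_mean^2),
            class = "occupancy_moments")
}

# Internal: moments and covariance matrix of p_n ~ exp(l1 n + l2 n^2) on
# 0..n_max, computed overflow-safely.
.maxent_stats <- function(l1, l2, n_max) {
  n <- 0:n_max
  e <- l1 * n + l2 * n^2
  e <- e - max(e)
  w <- exp(e)
  Z <- sum(w)
  p <- w / Z
  m1 <- sum(n * p)
  m2 <- sum(n^2 * p)
  m3 <- sum(n^3 * p)
  m4 <- sum(n^4 * p)
  list(p = p, m1 = m1, m2 = m2,
       J = matrix(c(m2 - m1^2,      m3 - m1 * m2,
                    m3 - m1 * m2,   m4 - m2^2), 2, 2),
       log_norm_shift = max(l1 * n + l2 * n^2))
}

#' Fit the two-moment maximum-entropy occupancy distribution
#'
#' The discrete occupancy distribution of maximum Shannon entropy subject to
#' normalization and the first two moments has the form
#' `p_n = exp(lambda0 + lambda1 n + lambda2 n^2)` on the non-negative
#' integers.  The Lagrange multipliers `(lambda1, lambda2)` are found by
#' Newton iteration (Jacobian = moment covariance matrix), initialized from
#' the matching continuous Gaussian (`lambda1 = <n>/sigma^2`,
#' `lambda2 = -1/(2 sigma^2)`); `lambda0` follows from normalization.
#'
#' @param moments an [occupancy_moments()] with `n_mean > 0`.
#' @param n_max support cap; default `max(50, ceiling(n_mean + 10 sigma))`.
#' @param tol relative moment-residual convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `maxent_distribution` with fields `lambda0`,
#'   `lambda1`, `lambda2`, `n_max`, `p` (probabilities on `0:n_max`),
#'   `moments`, `residuals`, `iterations`.
#' @examples
#' d <- fit_maxent(occupancy_moments(0.5, 0.55))
#' sum(d$p); -log(d$p[1])  # normalization; beta mu
#' @export
fit_maxent <- function(moments, n_max = NULL, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(moments, "occupancy_moments"))
  m1t <- moments$n_mean
  m2t <- moments$n2_mean
  if (m1t == 0) {  # deterministic empty volume
    n_max <- if (is.null(n_max)) 50L else as.integer(n_max)
    p <- c(1, rep(0, n_max))
    return(structure(list(lambda0 = 0, lambda1 = -Inf, lambda2 = 0,
                          n_max = n_max, p = p, moments = moments,
                          residuals = c(0, 0), iterations = 0L),
                     class = "maxent_distribution"))
  }
  sig2 <- moments$variance
  if (sig2 <= 0)
    stop("fit_maxent: zero variance is not representable on integer support ",
         "unless n_mean is an integer; not supported")
  sig <- sqrt(sig2)
  if (is.null(n_max)) n_max <- max(50L, as.integer(ceiling(m1t + 10 * sig)))
  n_max <- as.integer(n_max)
  if (n_max < ceiling(m1t + 2 * sig))
    stop("fit_maxent: n_max too small for the requested moments")

  l1 <- m1t / sig2
  l2 <- -1 / (2 * sig2)
  resid_norm <- function(l1x, l2x) {
    st <- .maxent_stats(l1x, l2x, n_max)
    r <- c(st$m1 - m1t, st$m2 - m2t)
    list(st = st, r = r,
         rel = abs(r) / c(max(m1t, 1e-300), max(m2t, 1e-300)))
  }
  cur <- resid_norm(l1, l2)
  it <- 0L
  while (!all(cur$rel < tol)) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(paste0("fit_maxent: no convergence after %d iterations ",
                          "(relative residuals %.3g, %.3g); the requested ",
                          "variance may be too large for a lambda2 < 0 ",
                          "solution on finite support"),
                   max_iter, cur$rel[1], cur$rel[2]))
    J <- cur$st$J
    # ridge-regularize a (near-)singular covariance; it only degrades the
    # step direction, not the converged solution
    if (!is.finite(rcond(J)) || rcond(J) < 1e-14)
      J <- J + diag(1e-10 * max(abs(J), 1), 2)
    step <- solve(J, cur$r)
    # backtracking: halve the step until the residual norm decreases
    fac <- 1
    repeat {
      cand <- resid_norm(l1 - fac * step[1], l2 - fac * step[2])
      if (all(is.finite(cand$r)) &&
          sum(cand$rel^2) < sum(cur$rel^2) * (1 - 1e-12) || fac < 1e-8) break
      fac <- fac / 2
    }
    l1 <- l1 - fac * step[1]
    l2 <- l2 - fac * step[2]
    cur <- cand
  }
  r <- cur$r
  # lambda0 from normalization: p_n = exp(l0 + l1 n + l2 n^2)
  n <- 0:n_max
  shift <- max(l1 * n + l2 * n^2)
  l0 <- -(shift + log(sum(exp(l1 * n + l2 * n^2 - shift))))
  p <- exp(l0 + l1 * n + l2 * n^2)
  if (p[n_max + 1L] > 1e-14)
    warning("fit_maxent: probability mass at the support cap exceeds 1e-14; ",
            "increase n_max")
  structure(list(lambda0 = l0, lambda1 = l1, lambda2 = l2,
                 n_max = n_max, p = p, moments = moments,
                 residuals = r, iterations = it),
            class = "maxent_distribution")
}

#' @export
print.maxent_distribution <- function(x, ...) {
  cat(sprintf(paste0("maxent_distribution: lambda0 = %.6g, lambda1 = %.6g, ",
                     "lambda2 = %.6g\n  n_max = %d, p0 = %.6g, %d Newton ",
                     "iterations\n"),
              x$lambda0, x$lambda1, x$lambda2, x$n_max, x$p[1], x$iterations))
  invisible(x)
}

#' Excess chemical potential from the maximum-entropy distribution
#'
#' `beta mu = -log p_0`; computed from `lambda0` directly
#' (`p_0 = exp(lambda0)`), which remains finite even when `p_0` underflows.
#'
#' @param dist a fitted [fit_maxent()] distribution.
#' @param T temperature (K), only for `units = "kJ/mol"`.
#' @param units `"kT"` or `"kJ/mol"`.
#' @return Excess chemical potential.
#' @export
mu_from_maxent <- function(dist, T = NULL, units = c("kT", "kJ/mol")) {
  stopifnot(inherits(dist, "maxent_distribution"))
  units <- match.arg(units)
  beta_mu <- -dist$lambda0
  if (units == "kT") return(beta_mu)
  if (is.null(T)) stop("mu_from_maxent: T required for kJ/mol output")
  beta_mu * .kB_kJmol * T
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum p log p` with the convention `0 log 0 = 0`.  Used to verify the
#' maximum-entropy property of fitted occupancy distributions.
#'
#' @param p probability vector.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
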