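#' Microscopic normalized variance
#'
#' For spherical observation volumes smaller than half the solvent diameter
#' at most one solvent center fits inside, the pair correlation function
#' does not contribute, and the normalized variance is exact:
#' `chi = 1 - (4 pi / 3) R^3 rho_w`.
#'
#' @param R observation sphere radius (A), >= 0.
#' @param sp a [state_point()].
#' @return Dimensionless normalized variance.
#' @export
chi_micro <- function(R, sp) {
  stopifnot(inherits(sp, "state_point"))
  if (any(!is.finite(R)) || any(R < 0)) stop("chi_micro: R must be >= 0")
  1 - (4 * pi / 3) * R^3 * sp$rho_w
}

#' Solve the interpolation coefficients of the large-cavity branch
#'
#' The large-cavity branch is a cubic polynomial in 1/R,
#' `chi_macro(R) = chi_inf + sigma1/R + sigma3/R^3` (the quadratic
#' coefficient vanishes identically for spherical volumes).  The two free
#' coefficients are fixed by requiring value and slope continuity with the
#' exact microscopic branch at `R = d_ww/2`, a 2x2 linear system with the
#' closed-form solution implemented here:
#' with `a = d_ww/2`, `A = 1 - eta - chi_inf`,
#' `sigma3 = 2 pi rho_w a^6 - A a^3 / 2` and `sigma1 = a A - sigma3 / a^2`.
#'
#' @param sp a [state_point()].
#' @param d_ww effective solvent diameter (A).
#' @return Named list `sigma1` (A), `sigma3` (A^3).
#' @export
solve_chi_coefficients <- function(sp, d_ww) {
  stopifnot(inherits(sp, "state_point"))
  if (!is.finite(d_ww) || d_ww <= 0) stop("solve_chi_coefficients: d_ww must be > 0")
  a <- d_ww / 2
  eta <- pi * sp$rho_w * d_ww^3 / 6
  chi_inf <- chi_infinity(sp)
  A <- 1 - eta - chi_inf
  sigma3 <- 2 * pi * sp$rho_w * a^6 - A * a^3 / 2
  sigma1 <- a * A - sigma3 / a^2
  list(sigma1 = sigma1, sigma3 = sigma3)
}

#' Interpolated normalized-variance model
#'
#' Bundles a solvent state point, the effective solvent diameter and the
#' interpolation coefficients into a model object whose [chi()] method
#' evaluates the normalized occupancy variance at any radius: the exact
#' microscopic expression up to `R = d_ww/2` and the smoothly matched
#' cubic-in-1/R beyond.  Construction verifies the continuity residuals
#' (value to 1e-12, slope to 1e-8 relative).
#'
#' @param sp a [state_point()].
#' @param d_ww effective solvent diameter (A); 2.647 A is a sensible
#'   water default.
#' @return An object of class `chi_model` with fields `d_ww`, `sp`,
#'   `chi_inf`, `sigma1`, `sigma2` (identically 0), `sigma3`, `eta`.
#' @examples
#' m <- chi_model(state_point(298.15, 0.0334, 4.5e-5), d_ww = 2.647)
#' chi(3.3, m)
#' @export
chi_model <- function(sp, d_ww = 2.647) {
  stopifnot(inherits(sp, "state_point"))
  if (!is.finite(d_ww) || d_ww <= 0) stop("chi_model: d_ww must be > 0")
  co <- solve_chi_coefficients(sp, d_ww)
  m <- structure(list(d_ww = d_ww, sp = sp,
                      chi_inf = chi_infinity(sp),
                      sigma1 = co$sigma1, sigma2 = 0, sigma3 = co$sigma3,
                      eta = pi * sp$rho_w * d_ww^3 / 6),
                 class = "chi_model")
  a <- d_ww / 2
  val_resid <- abs(.chi_macro(a, m) - chi_micro(a, sp))
  slope_micro <- -4 * pi * sp$rho_w * a^2
  slope_macro <- -m$sigma1 / a^2 - 3 * m$sigma3 / a^4
  slope_resid <- abs(slope_macro - slope_micro) / max(abs(slope_micro), 1e-300)
  if (val_resid > 1e-12 || slope_resid > 1e-8)
    stop("chi_model: continuity residuals exceed tolerance (internal error)")
  m
}

#' @export
print.chi_model <- function(x, ...) {
  cat(sprintf(paste0("chi_model: d_ww = %.4g A, eta = %.4f, chi_inf = %.5g\n",
                     "  sigma1 = %.5g A, sigma3 = %.5g A^3\n"),
              x$d_ww, x$eta, x$chi_inf, x$sigma1, x$sigma3))
  invisible(x)
}

.chi_macro <- function(R, model) {
  model$chi_inf + model$sigma1 / R + model$sigma3 / R^3
}

#' Evaluate the interpolated normalized variance
#'
#' Piecewise evaluation: exact microscopic branch for `R <= d_ww/2`
#' (the boundary point belongs to the microscopic branch; both branches
#' agree there), cubic-in-1/R branch beyond.  Vectorized in `R`.
#'
#' @param R radius or vector of radii (A), >= 0.
#' @param model a [chi_model()].
#' @return Normalized variance values, same length as `R`.
#' @export
chi <- function(R, model) {
  stopifnot(inherits(model, "chi_model"))
  if (any(!is.finite(R)) || any(R < 0)) stop("chi: R must be >= 0")
  a <- model$d_ww / 2
  out <- numeric(length(R))
  lo <- R <= a
  out[lo] <- chi_micro(R[lo], model$sp)
  out[!lo] <- .chi_macro(R[!lo], model)
  out
}

#' Mean occupancy of a spherical observation volume
#'
#' `<n> = (4 pi / 3) R^3 rho_w`.
#'
#' @param R radius (A).
#' @param model a [chi_model()] (or a [state_point()]).
#' @return Mean solvent occupancy.
#' @export
occupancy_mean <- function(R, model) {
  sp <- if (inherits(model, "chi_model")) model$sp else model
  stopifnot(inherits(sp, "state_point"))
  (4 * pi / 3) * R^3 * sp$rho_w
}

#' Occupancy variance from the interpolated model
#'
#' `sigma^2 = chi(R) * <n>` with `<n> = (4 pi / 3) R^3 rho_w`.
#'
#' @param R radius (A), >= 0.
#' @param model a [chi_model()].
#' @return Occupancy variance (>= 0).
#' @export
occupancy_variance <- function(R, model) {
  stopifnot(inherits(model, "chi_model"))
  v <- chi(R, model) * occupancy_mean(R, model)
  pmax(v, 0)
}
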