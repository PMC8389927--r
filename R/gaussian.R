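#' Continuous Gaussian occupancy statistics
#'
#' @param n_mean mean occupancy `<n>` (>= 0).
#' @param variance occupancy variance `sigma^2` (> 0 when `n_mean` > 0).
#' @return Object of class `gaussian_occupancy` with fields `n_mean`,
#'   `variance`, `chi` (= variance / n_mean).
#' @export
gaussian_occupancy <- function(n_mean, variance) {
  if (!is.finite(n_mean) || n_mean < 0)
    stop("gaussian_occupancy: n_mean must be >= 0")
  if (!is.finite(variance) || (n_mean > 0 && variance <= 0))
    stop("gaussian_occupancy: variance must be > 0 for n_mean > 0")
  structure(list(n_mean = n_mean, variance = variance,
                 chi = if (n_mean > 0) variance / n_mean else NA_real_),
            class = "gaussian_occupancy")
}

#' Gaussian occupancy model from the interpolated variance theory
#'
#' Convenience constructor: `<n> = (4 pi / 3) R^3 rho_w`,
#' `sigma^2 = chi(R) <n>`.
#'
#' @param R observation sphere radius (A).
#' @param model a [chi_model()].
#' @return A [gaussian_occupancy()] object.
#' @export
gaussian_occupancy_from_model <- function(R, model) {
  gaussian_occupancy(occupancy_mean(R, model), occupancy_variance(R, model))
}

#' Gaussian occupancy probability density
#'
#' Normal density with mean `<n>` and variance `sigma^2`, the continuous
#' approximation to the discrete occupancy distribution.  The normalization
#' extends over negative `n`; see [negative_mass_diagnostic()].
#'
#' @param n occupancy value(s), treated as continuous.
#' @param occ a [gaussian_occupancy()].
#' @return Density values.
#' @export
p_n_gaussian <- function(n, occ) {
  stopifnot(inherits(occ, "gaussian_occupancy"))
  if (occ$variance <= 0) stop("p_n_gaussian: variance must be > 0")
  stats::dnorm(n, mean = occ$n_mean, sd = sqrt(occ$variance))
}

#' Excess chemical potential of a hard solute (Gaussian model)
#'
#' The reversible work to empty the observation volume, from the Gaussian
#' occupancy model evaluated at `n = 0`:
#' `beta mu = <n> / (2 chi) + log(2 pi <n> chi) / 2`,
#' algebraically identical to `-log p_n_gaussian(0)`.
#' Dimensionless (`beta mu`); multiply by `k_B T` for energy units.
#'
#' @param occ a [gaussian_occupancy()] with `n_mean > 0`.
#' @param T temperature (K), used only when `units = "kJ/mol"`.
#' @param units `"kT"` (default, returns beta*mu) or `"kJ/mol"`.
#' @return Excess chemical potential.
#' @examples
#' mu_excess(gaussian_occupancy(5.03, 1.24))  # about 11.2 kT
#' @export
mu_excess <- function(occ, T = NULL, units = c("kT", "kJ/mol")) {
  stopifnot(inherits(occ, "gaussian_occupancy"))
  units <- match.arg(units)
  if (occ$n_mean <= 0)
    stop("mu_excess: zero mean occupancy; use mu_exact_small() for ",
         "sub-diameter solutes")
  if (occ$chi <= 0) stop("mu_excess: chi must be > 0")
  beta_mu <- occ$n_mean / (2 * occ$chi) + 0.5 * log(2 * pi * occ$n_mean * occ$chi)
  if (units == "kT") return(beta_mu)
  if (is.null(T)) stop("mu_excess: T required for kJ/mol output")
  beta_mu * .kB_kJmol * T
}

#' Exact excess chemical potential for sub-diameter solutes
#'
#' For `R < d_ww/2` at most one solvent center fits in the cavity and the
#' empty-volume probability is exact:
#' `beta mu = -log(1 - (4 pi / 3) R^3 rho_w)`.
#'
#' @param R solute radius (A), with `(4 pi / 3) R^3 rho_w < 1`.
#' @param rho_w solvent number density (A^-3).
#' @param T temperature (K), only for `units = "kJ/mol"`.
#' @param units `"kT"` or `"kJ/mol"`.
#' @return Excess chemical potential.
#' @export
mu_exact_small <- function(R, rho_w, T = NULL, units = c("kT", "kJ/mol")) {
  units <- match.arg(units)
  if (any(R < 0)) stop("mu_exact_small: R must be >= 0")
  p0 <- 1 - (4 * pi / 3) * R^3 * rho_w
  if (any(p0 <= 0))
    stop("mu_exact_small: occupied fraction >= 1; solute too large for the ",
         "exact sub-diameter branch")
  beta_mu <- -log(p0)
  if (units == "kT") return(beta_mu)
  if (is.null(T)) stop("mu_exact_small: T required for kJ/mol output")
  beta_mu * .kB_kJmol * T
}

#' Probability mass at negative occupancy
#'
#' The continuous Gaussian distribution assigns mass to `n < 0`:
#' `Phi(-<n>/sigma)`.  This mass is reported as a diagnostic and never
#' subtracted; it is negligible for atomic-sized solutes.
#'
#' @param occ a [gaussian_occupancy()].
#' @param warn_above issue a warning when the mass exceeds this value.
#' @return Probability in [0, 1].
#' @export
negative_mass_diagnostic <- function(occ, warn_above = 1e-3) {
  stopifnot(inherits(occ, "gaussian_occupancy"))
  if (occ$variance <= 0) stop("negative_mass_diagnostic: variance must be > 0")
  p <- pnorm(-occ$n_mean / sqrt(occ$variance))
  if (p > warn_above)
    warning(sprintf(paste0("negative occupancy mass %.3g exceeds %.1g: ",
                           "Gaussian approximation is questionable here"),
                    p, warn_above))
  p
}

#' Excess chemical potential across all solute sizes
#'
#' Dispatches to the exact sub-diameter expression for `R < d_ww/2` and to
#' the Gaussian interpolated-variance expression at `R >= d_ww/2`.
#' Vectorized in `R`.
#'
#' @param R solute radii (A).
#' @param model a [chi_model()].
#' @param units `"kT"` or `"kJ/mol"`.
#' @return `beta mu` values (or kJ/mol).
#' @export
mu_igft <- function(R, model, units = c("kT", "kJ/mol")) {
  stopifnot(inherits(model, "chi_model"))
  units <- match.arg(units)
  a <- model$d_ww / 2
  vapply(R, function(Ri) {
    if (Ri < a) {
      mu_exact_small(Ri, model$sp$rho_w)
    } else {
      mu_excess(gaussian_occupancy_from_model(Ri, model))
    }
  }, numeric(1)) * if (units == "kT") 1 else .kB_kJmol * model$sp$T
}
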