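#' Excess chemical potential versus temperature
#'
#' For each temperature on the grid, interpolates the equation of state,
#' rebuilds the fluctuation model at that state point and evaluates the
#' hard-sphere excess chemical potential (exact sub-diameter branch below
#' `d_ww/2`, Gaussian interpolated-variance branch at and above).
#'
#' @param eos an [eos_table()].
#' @param d_ww effective solvent diameter (A).
#' @param R solute radius (A).
#' @param T_grid temperatures (K) within the table range.
#' @param units `"kT"` returns beta*mu, `"kJ/mol"` energy units (default:
#'   energy units, which is what the temperature decomposition needs).
#' @return `data.frame` with columns `T`, `beta_mu`, `mu` (kJ/mol).
#' @export
mu_vs_T <- function(eos, d_ww, R, T_grid, units = "kJ/mol") {
  stopifnot(inherits(eos, "eos_table"))
  beta_mu <- vapply(T_grid, function(Ti) {
    sp <- interpolate_state(eos, Ti)
    mu_igft(R, chi_model(sp, d_ww))
  }, numeric(1))
  data.frame(T = T_grid, beta_mu = beta_mu,
             mu = beta_mu * .kB_kJmol * T_grid)
}

# Basis of the five-parameter temperature fit.  The quadratic-in-T heat
# capacity c(T) = -a3 - 2 a4 T - 6 a5 T (T - T0) follows identically from
# mu(T) = a1 + a2 (T-T0) + a3 [T log(T/T0) - (T-T0)] + a4 (T-T0)^2
#         + a5 (T-T0)^3.
.thermo_basis <- function(T, T0) {
  cbind(b1 = rep(1, length(T)),
        b2 = T - T0,
        b3 = T * log(T / T0) - (T - T0),
        b4 = (T - T0)^2,
        b5 = (T - T0)^3)
}

#' Fit the five-parameter temperature decomposition
#'
#' Unweighted linear least squares of `mu(T)` onto the basis
#' `{1, (T-T0), T log(T/T0) - (T-T0), (T-T0)^2, (T-T0)^3}`, whose
#' closed-form temperature derivatives give the hydration entropy,
#' enthalpy and a heat capacity quadratic in temperature,
#' `c(T) = -a3 - 2 a4 T - 6 a5 T (T - T0)`.
#'
#' @param T_grid temperatures (K), at least 5 points spanning >= 100 K.
#' @param mu_values chemical potentials (energy units; the coefficients
#'   inherit these units).
#' @param T0 reference temperature (K), default 298.15.
#' @param rcond_min conditioning guard on the design matrix.
#' @return Object of class `thermo_fit`: `a` (a1..a5), `T0`, `T_range`,
#'   `rms_residual`, `units` attribute-free.
#' @export
fit_thermo <- function(T_grid, mu_values, T0 = 298.15, rcond_min = 1e-12) {
  if (length(T_grid) < 5L)
    stop("fit_thermo: need at least 5 temperature points")
  if (diff(range(T_grid)) < 100)
    stop("fit_thermo: temperature span below 100 K; the five-parameter fit ",
         "is ill-conditioned on narrow ranges")
  if (length(mu_values) != length(T_grid))
    stop("fit_thermo: mu_values must match T_grid")
  X <- .thermo_basis(T_grid, T0)
  qrX <- qr(X)
  if (qrX$rank < 5L)
    stop("fit_thermo: rank-deficient design; widen the temperature range")
  a <- qr.coef(qrX, mu_values)
  resid <- mu_values - drop(X %*% a)
  structure(list(a = unname(a), T0 = T0, T_range = range(T_grid),
                 rms_residual = sqrt(mean(resid^2))),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("thermo_fit: T0 = %.2f K, T in [%.1f, %.1f] K, rms = %.3g\n",
              x$T0, x$T_range[1], x$T_range[2], x$rms_residual))
  cat("  a =", paste(sprintf("%.6g", x$a), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted mu(T)
#'
#' @param fit a [fit_thermo()] object.
#' @param T temperatures (K).
#' @return Fitted chemical potential values.
#' @export
mu_from_fit <- function(fit, T) {
  stopifnot(inherits(fit, "thermo_fit"))
  drop(.thermo_basis(T, fit$T0) %*% fit$a)
}

#' Hydration enthalpy, entropy and heat capacity from a temperature fit
#'
#' Closed-form derivatives of the fitted expression:
#' `s = -d mu/dT`, `h = mu + T s` (so that `mu = h - T s` holds
#' identically), `c = -T d^2 mu/dT^2 = -a3 - 2 a4 T - 6 a5 T (T - T0)`.
#' Energy units follow the units of the fitted `mu`.
#'
#' @param fit a [fit_thermo()] object.
#' @param T temperatures (K); values outside the fit domain trigger a
#'   warning.
#' @return `data.frame` with columns `T`, `mu`, `h`, `s`, `Ts`, `c`.
#' @export
enthalpy_entropy_heatcap <- function(fit, T) {
  stopifnot(inherits(fit, "thermo_fit"))
  if (any(T < fit$T_range[1] - 1e-9) || any(T > fit$T_range[2] + 1e-9))
    warning("enthalpy_entropy_heatcap: extrapolating beyond the fit domain")
  a <- fit$a; T0 <- fit$T0
  mu <- mu_from_fit(fit, T)
  dmu <- a[2] + a[3] * log(T / T0) + 2 * a[4] * (T - T0) + 3 * a[5] * (T - T0)^2
  s <- -dmu
  h <- mu + T * s
  c <- -a[3] - 2 * a[4] * T - 6 * a[5] * T * (T - T0)
  data.frame(T = T, mu = mu, h = h, s = s, Ts = T * s, c = c)
}

#' Temperature of minimum solubility
#'
#' The Ostwald solubility `K_eq = exp(-beta mu)` of a hard solute is
#' minimal where the hydration enthalpy crosses zero; this solves
#' `h(T) = 0` on the fit domain by Brent's method to 0.01 K.
#'
#' @param fit a [fit_thermo()] object.
#' @param tol root tolerance (K).
#' @return The root temperature (K), or `NA` with attribute
#'   `reason = "no sign change"` when `h` does not change sign in range.
#' @export
solubility_minimum_T <- function(fit, tol = 0.01) {
  stopifnot(inherits(fit, "thermo_fit"))
  h_of <- function(T) enthalpy_entropy_heatcap(fit, T)$h
  Ts <- seq(fit$T_range[1], fit$T_range[2], length.out = 400L)
  hv <- h_of(Ts)
  sgn <- which(hv[-1] * hv[-length(hv)] <= 0)
  if (length(sgn) == 0L)
    return(structure(NA_real_, reason = "no sign change"))
  i <- sgn[1]
  uniroot(h_of, c(Ts[i], Ts[i + 1L]), tol = tol)$root
}

#' Ostwald solubility coefficient
#'
#' `K_eq = exp(-beta mu)`, the equilibrium ratio of solute number density
#' in solution to that in the ideal gas phase.
#'
#' @param beta_mu dimensionless excess chemical potential(s).
#' @return `K_eq` value(s).
#' @export
ostwald_coefficient <- function(beta_mu) {
  if (any(!is.finite(beta_mu))) stop("ostwald_coefficient: beta_mu must be finite")
  exp(-beta_mu)
}

#' Entropy-convergence temperature for a solute size
#'
#' The temperature at which the hydration entropies of a solute and one
#' differentially larger coincide, i.e. `d s/d R = 0` at constant pressure.
#' Implemented through the temperature fit: `mu(T)` curves are computed at
#' `R - dR` and `R + dR`, each fitted with [fit_thermo()], and the root of
#' the entropy difference over T is located to `tol` K.
#'
#' @param eos an [eos_table()] spanning a wide temperature range.
#' @param d_ww effective solvent diameter (A).
#' @param R solute radius (A), at or above `d_ww/2` for the fluctuation
#'   branch.
#' @param dR centered half-step in radius (A), default 0.01.
#' @param T0 fit reference temperature (K).
#' @param n_T fit grid size over the table range.
#' @param tol root tolerance (K).
#' @return Root temperature (K); `NA` with a `reason` attribute when the
#'   entropy difference does not change sign in range (the boundary values
#'   are reported in attribute `boundary`), or when it is identically zero
#'   (`reason = "s independent of R"`).
#' @export
entropy_convergence_T <- function(eos, d_ww, R, dR = 0.01, T0 = 298.15,
                                  n_T = 60L, tol = 0.1) {
  stopifnot(inherits(eos, "eos_table"))
  T_grid <- seq(min(eos$T), max(eos$T), length.out = n_T)
  s_of <- function(Ri) {
    mt <- mu_vs_T(eos, d_ww, Ri, T_grid)
    fit <- fit_thermo(T_grid, mt$mu, T0 = T0)
    function(T) enthalpy_entropy_heatcap(fit, T)$s
  }
  s_lo <- s_of(R - dR)
  s_hi <- s_of(R + dR)
  f <- function(T) s_hi(T) - s_lo(T)
  Ts <- seq(min(eos$T), max(eos$T), length.out = 400L)
  fv <- f(Ts)
  if (all(abs(fv) < 1e-13))
    return(structure(NA_real_, reason = "s independent of R"))
  sgn <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(sgn) == 0L)
    return(structure(NA_real_, reason = "no sign change",
                     boundary = c(fv[1], fv[length(fv)])))
  i <- sgn[1]
  uniroot(f, c(Ts[i], Ts[i + 1L]), tol = tol)$root
}

#' Point-solute entropy-convergence temperature
#'
#' In the point-solute limit the exact sub-diameter chemical potential
#' yields the closed-form convergence condition `T * alpha(T) = 1`, where
#' `alpha` is the solvent thermal expansion coefficient.  Solved by
#' root-finding on the equation-of-state table to `tol` K.
#'
#' @param eos an [eos_table()].
#' @param tol root tolerance (K).
#' @param use_table_alpha use the table's `alpha` column when present
#'   (interpolated linearly) instead of differentiating the density.
#' @return Root temperature (K), or `NA` with `reason = "no root in range"`.
#' @export
t_conv_point_solute <- function(eos, tol = 0.1, use_table_alpha = FALSE) {
  stopifnot(inherits(eos, "eos_table"))
  if (use_table_alpha && !is.null(eos$alpha)) {
    af <- approxfun(eos$T, eos$alpha)
  } else {
    af <- function(T) vapply(T, function(Ti)
      suppressWarnings(thermal_expansion(eos, Ti)), numeric(1))
  }
  f <- function(T) T * af(T) - 1
  Ts <- seq(min(eos$T), max(eos$T), length.out = 400L)
  fv <- f(Ts)
  sgn <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(sgn) == 0L)
    return(structure(NA_real_, reason = "no root in range"))
  i <- sgn[1]
  uniroot(f, c(Ts[i], Ts[i + 1L]), tol = tol)$root
}
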