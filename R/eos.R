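#' Solvent state point
#'
#' A single thermodynamic state of the solvent: the only physical inputs the
#' fluctuation theory needs.  Units are Kelvin, particles per cubic Angstrom
#' and reciprocal bar throughout.
#'
#' @param T temperature (K), > 0.
#' @param rho_w solvent number density (A^-3), > 0.
#' @param kappa_T isothermal compressibility (bar^-1), > 0.
#' @param alpha optional thermal expansion coefficient (K^-1).
#' @param P_label optional pressure tag (bar); metadata only.
#' @return An object of class `state_point`.
#' @examples
#' sp <- state_point(T = 298.15, rho_w = 0.0334, kappa_T = 4.5e-5)
#' chi_infinity(sp)
#' @export
state_point <- function(T, rho_w, kappa_T, alpha = NA_real_, P_label = NA_real_) {
  stopifnot(is.numeric(T), is.numeric(rho_w), is.numeric(kappa_T),
            length(T) == 1L, length(rho_w) == 1L, length(kappa_T) == 1L)
  if (!is.finite(T) || T <= 0) stop("state_point: T must be finite and > 0")
  if (!is.finite(rho_w) || rho_w <= 0) stop("state_point: rho_w must be finite and > 0")
  if (!is.finite(kappa_T) || kappa_T <= 0) stop("state_point: kappa_T must be finite and > 0")
  if (!is.na(alpha) && !is.finite(alpha)) stop("state_point: alpha must be finite if given")
  structure(list(T = T, rho_w = rho_w, kappa_T = kappa_T,
                 alpha = alpha, P_label = P_label),
            class = "state_point")
}

#' @export
print.state_point <- function(x, ...) {
  cat(sprintf("state_point: T = %.3f K, rho_w = %.6g A^-3, kappa_T = %.4g bar^-1\n",
              x$T, x$rho_w, x$kappa_T))
  if (!is.na(x$alpha)) cat(sprintf("  alpha = %.4g K^-1\n", x$alpha))
  invisible(x)
}

#' Equation-of-state table
#'
#' An ordered set of solvent state points versus temperature, interpolated by
#' [interpolate_state()].  Densities and compressibilities must be supplied by
#' the user (from experiment or simulation); the package ships no solvent data
#' as ground truth.
#'
#' @param T temperatures (K), strictly increasing, length >= 2.
#' @param rho_w number densities (A^-3) at each temperature.
#' @param kappa_T isothermal compressibilities (bar^-1).
#' @param alpha optional thermal expansion coefficients (K^-1).
#' @param source free-text provenance string.
#' @return An object of class `eos_table`.
#' @seealso [read_eos_table()], [water_like_eos()]
#' @export
eos_table <- function(T, rho_w, kappa_T, alpha = NULL, source = "") {
  n <- length(T)
  if (n < 2L) stop("eos_table: need at least 2 state points for interpolation")
  if (length(rho_w) != n || length(kappa_T) != n)
    stop("eos_table: T, rho_w, kappa_T must have equal length")
  if (any(diff(T) <= 0)) stop("eos_table: T must be strictly increasing")
  if (any(!is.finite(T)) || any(T <= 0)) stop("eos_table: T must be finite and > 0")
  if (any(!is.finite(rho_w)) || any(rho_w <= 0)) stop("eos_table: rho_w must be > 0")
  if (any(!is.finite(kappa_T)) || any(kappa_T <= 0)) stop("eos_table: kappa_T must be > 0")
  if (!is.null(alpha) && length(alpha) != n)
    stop("eos_table: alpha must match length of T")
  structure(list(T = as.numeric(T), rho_w = as.numeric(rho_w),
                 kappa_T = as.numeric(kappa_T),
                 alpha = if (is.null(alpha)) NULL else as.numeric(alpha),
                 source = source),
            class = "eos_table")
}

#' @export
print.eos_table <- function(x, ...) {
  cat(sprintf("eos_table: %d state points, T in [%.2f, %.2f] K\n",
              length(x$T), min(x$T), max(x$T)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Read an equation-of-state table from delimited text
#'
#' Expects a header line with columns `T_K, rho_A3, kappaT_bar` and an
#' optional `alpha_K` column; `#` lines are comments.  Comma, whitespace or
#' tab delimited.
#'
#' @param path file path.
#' @return An [eos_table()].
#' @export
read_eos_table <- function(path) {
  if (!file.exists(path)) stop("read_eos_table: file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "", comment.char = "#",
                   blank.lines.skip = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) == 1L)  # comma-delimited fallback
    df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                     blank.lines.skip = TRUE, stringsAsFactors = FALSE)
  need <- c("T_K", "rho_A3", "kappaT_bar")
  if (!all(need %in% names(df)))
    stop("read_eos_table: header must contain columns ",
         paste(need, collapse = ", "))
  eos_table(df$T_K, df$rho_A3, df$kappaT_bar,
            alpha = if ("alpha_K" %in% names(df)) df$alpha_K else NULL,
            source = path)
}

#' Write an equation-of-state table to delimited text
#'
#' @param eos an [eos_table()].
#' @param path output file path.
#' @export
write_eos_table <- function(eos, path) {
  df <- data.frame(T_K = eos$T, rho_A3 = eos$rho_w, kappaT_bar = eos$kappa_T)
  if (!is.null(eos$alpha)) df$alpha_K <- eos$alpha
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Macroscopic normalized-variance limit
#'
#' In an infinitely large observation volume the normalized occupancy
#' variance reduces to the Kirkwood-Buff compressibility value
#' `k_B * T * rho_w * kappa_T` (dimensionless).  This anchors the
#' large-radius branch of the interpolation.
#'
#' @param sp a [state_point()].
#' @return Dimensionless normalized variance limit (> 0, or 0 in the
#'   incompressible limit `kappa_T -> 0`).
#' @examples
#' chi_infinity(state_point(298.15, 0.0334, 4.5e-5))  # about 0.062
#' @export
chi_infinity <- function(sp) {
  stopifnot(inherits(sp, "state_point"))
  .kB_barA3 * sp$T * sp$rho_w * sp$kappa_T
}

#' Solvent packing fraction
#'
#' `eta = pi * rho_w * d_ww^3 / 6`, the volume fraction occupied by solvent
#' spheres of effective diameter `d_ww`.
#'
#' @param sp a [state_point()] (only `rho_w` is used).
#' @param d_ww effective solvent diameter (A), > 0.
#' @return Dimensionless packing fraction.
#' @export
packing_fraction <- function(sp, d_ww) {
  stopifnot(inherits(sp, "state_point"))
  if (!is.finite(d_ww) || d_ww <= 0) stop("packing_fraction: d_ww must be > 0")
  eta <- pi * sp$rho_w * d_ww^3 / 6
  if (eta >= 1) warning("packing_fraction: eta >= 1; unphysical for a liquid")
  eta
}

#' Effective macroscopic cavity pressure
#'
#' The Gaussian free-energy expression implies an effective pressure
#' `1/(2 kappa_T)` acting on a macroscopic cavity surface; for ambient water
#' this is on the order of 1e4 bar, which is why the Gaussian model must not
#' be extrapolated to macroscopic solutes.
#'
#' @param kappa_T isothermal compressibility (bar^-1).
#' @return Pressure in bar.
#' @export
effective_macroscopic_pressure <- function(kappa_T) {
  if (!is.finite(kappa_T) || kappa_T <= 0)
    stop("effective_macroscopic_pressure: kappa_T must be > 0")
  1 / (2 * kappa_T)
}

# Internal: interpolants for an eos_table.  method "monotone" uses
# monotonicity-preserving piecewise cubics (no spline overshoot in the steep
# high-T growth of kappa_T); "linear" is the fallback.
.eos_funs <- function(table, method = c("monotone", "linear")) {
  method <- match.arg(method)
  if (method == "monotone" && length(table$T) >= 3L) {
    list(rho = splinefun(table$T, table$rho_w, method = "monoH.FC"),
         kap = splinefun(table$T, table$kappa_T, method = "monoH.FC"))
  } else {
    list(rho = approxfun(table$T, table$rho_w, rule = 1),
         kap = approxfun(table$T, table$kappa_T, rule = 1))
  }
}

#' Interpolate an equation-of-state table at a temperature
#'
#' Monotonicity-safe piecewise-cubic interpolation of density and
#' compressibility (exact at table nodes); linear interpolation available as
#' a fallback.  No extrapolation outside the table range.
#'
#' @param table an [eos_table()].
#' @param T temperature (K) within the table range.
#' @param method `"monotone"` (default) or `"linear"`.
#' @return A [state_point()] at `T`.
#' @export
interpolate_state <- function(table, T, method = c("monotone", "linear")) {
  stopifnot(inherits(table, "eos_table"))
  method <- match.arg(method)
  if (!is.finite(T) || T < min(table$T) || T > max(table$T))
    stop(sprintf("interpolate_state: T = %g outside table range [%g, %g]",
                 T, min(table$T), max(table$T)))
  f <- .eos_funs(table, method)
  state_point(T = T, rho_w = f$rho(T), kappa_T = f$kap(T))
}

#' Thermal expansion coefficient from an equation-of-state table
#'
#' `alpha = -d ln(rho_w)/dT` at constant pressure, by centered finite
#' difference on the density interpolant.  The step is
#' `min(1 K, local node spacing / 10)`.  At the table boundary a one-sided
#' difference is used with a warning.
#'
#' @param table an [eos_table()].
#' @param T temperature (K) within the table range.
#' @param method interpolation method, see [interpolate_state()].
#' @return `alpha` in K^-1.
#' @export
thermal_expansion <- function(table, T, method = c("monotone", "linear")) {
  stopifnot(inherits(table, "eos_table"))
  method <- match.arg(method)
  Tmin <- min(table$T); Tmax <- max(table$T)
  if (!is.finite(T) || T < Tmin || T > Tmax)
    stop("thermal_expansion: T outside table range")
  # local node spacing around T
  idx <- findInterval(T, table$T, all.inside = TRUE)
  h_loc <- table$T[idx + 1L] - table$T[idx]
  h <- min(1, h_loc / 10)
  f <- .eos_funs(table, method)
  if (T - h >= Tmin && T + h <= Tmax) {
    dlnrho <- (log(f$rho(T + h)) - log(f$rho(T - h))) / (2 * h)
  } else if (T + h <= Tmax) {
    warning("thermal_expansion: boundary T, using forward difference")
    dlnrho <- (log(f$rho(T + h)) - log(f$rho(T))) / h
  } else {
    warning("thermal_expansion: boundary T, using backward difference")
    dlnrho <- (log(f$rho(T)) - log(f$rho(T - h))) / h
  }
  -dlnrho
}

#' Synthetic water-like equation of state
#'
#' A smooth, fully synthetic equation of state emulating compressed liquid
#' water along an elevated-pressure isobar: density decreases monotonically
#' with temperature, compressibility grows toward the hot expanded liquid.
#' It is generated from closed-form expressions
#' `rho(T) = rho0 * exp(-(a0*(T-T0) + a1*(T-T0)^2/2))` and
#' `kappa(T) = kappa0 * exp(b1*(T-T0) + b2*(T-T0)^2/2)`, with defaults
#' chosen to track compressed-liquid-water magnitudes
#' (`rho ~ 0.0334 A^-3`, `kappa ~ 4.5e-5 bar^-1` at 298.15 K), a thermal
#' expansion coefficient rising from about 2.7e-4 K^-1 at ambient to about
#' 2e-3 K^-1 in the hot liquid (so the point-solute condition
#' `T * alpha = 1` has a root inside the table), and a compressibility with
#' a shallow minimum near 320 K followed by accelerating growth toward the
#' hot expanded liquid.  It is illustrative scaffolding for examples and
#' validation, not measured solvent data.
#'
#' @param T_min,T_max temperature range (K).
#' @param n_points number of table rows.
#' @param rho0 density at `T0` (A^-3).
#' @param kappa0 compressibility at `T0` (bar^-1).
#' @param a0 thermal expansion at `T0` (K^-1).
#' @param a1 linear growth rate of the expansion coefficient (K^-2).
#' @param b1,b2 linear and quadratic rates of `log kappa(T)`; the defaults
#'   place the compressibility minimum at `T0 - b1/b2` (about 320 K).
#' @param T0 reference temperature (K).
#' @return An [eos_table()] with analytic `alpha` included.
#' @export
water_like_eos <- function(T_min = 260, T_max = 600, n_points = 69,
                           rho0 = 0.0334, kappa0 = 4.5e-5,
                           a0 = 2.7e-4, a1 = 6.5e-6,
                           b1 = -1.158e-3, b2 = 5.265e-5,
                           T0 = 298.15) {
  T <- seq(T_min, T_max, length.out = n_points)
  dT <- T - T0
  rho <- rho0 * exp(-(a0 * dT + a1 * dT^2 / 2))
  kap <- kappa0 * exp(b1 * dT + b2 * dT^2 / 2)
  alpha <- a0 + a1 * dT
  eos_table(T, rho, kap, alpha = alpha,
            source = "synthetic water-like EOS (closed-form, illustrative)")
}
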