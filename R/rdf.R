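#' Radial distribution function table
#'
#' @param r radial grid (A), strictly increasing, first point >= 0.
#' @param g pair correlation values (dimensionless, >= 0, finite).
#' @return Object of class `rdf_table` with fields `r`, `g`, `r_max`.
#' @export
rdf_table <- function(r, g) {
  if (length(r) != length(g) || length(r) < 2L)
    stop("rdf_table: r and g must have equal length >= 2")
  if (any(!is.finite(r)) || r[1] < 0 || any(diff(r) <= 0))
    stop("rdf_table: r must be non-negative and strictly increasing")
  if (any(!is.finite(g)) || any(g < 0))
    stop("rdf_table: g must be finite and non-negative")
  structure(list(r = as.numeric(r), g = as.numeric(g), r_max = r[length(r)]),
            class = "rdf_table")
}

#' Read a two-column radial distribution function file
#'
#' Plain text, columns `r_A g`, `#` comments, no header required (a header
#' line is tolerated and skipped if non-numeric).
#'
#' @param path file path.
#' @return An [rdf_table()].
#' @export
read_rdf <- function(path) {
  if (!file.exists(path)) stop("read_rdf: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  first <- strsplit(trimws(lines[1]), "[,[:space:]]+")[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first))))) lines <- lines[-1]
  df <- read.table(text = lines, header = FALSE,
                   sep = if (grepl(",", lines[1])) "," else "")
  rdf_table(df[[1]], df[[2]])
}

#' Sphere-sphere intersection (lens) volume
#'
#' Volume of the intersection of two spheres of equal radius `R` whose
#' centers are a distance `r` apart:
#' `(pi/12) (2R - r)^2 (4R + r)` when the separation is below `2R`, zero
#' beyond.  This is the
#' geometric kernel that reduces the double volume integral of the pair
#' correlation function over a spherical domain to one dimension.
#'
#' @param r center separation (A), >= 0 (vectorized).
#' @param R sphere radius (A), > 0.
#' @return Intersection volume (A^3).
#' @export
lens_volume <- function(r, R) {
  if (any(!is.finite(r)) || any(r < 0)) stop("lens_volume: r must be >= 0")
  if (!is.finite(R) || R <= 0) stop("lens_volume: R must be > 0")
  ifelse(r < 2 * R, (pi / 12) * (2 * R - r)^2 * (4 * R + r), 0)
}

# Internal: linear interpolation of g with g = 1 assumed beyond r_max and
# g = g[1] below the first node (RDF tables normally start at r = 0).
.g_fun <- function(rdf) {
  approxfun(rdf$r, rdf$g, rule = 2, yleft = rdf$g[1], yright = 1)
}

#' Normalized variance from a pair correlation function
#'
#' Evaluates the fluctuation integral
#' `chi = 1 + (rho_w / V) * int_0^{2R} 4 pi r^2 (g(r) - 1) v_lens(r, R) dr`
#' with `V = (4 pi / 3) R^3`, by trapezoidal quadrature on the native grid
#' refined to a step of at most `dr_max` (default 0.01 A); `g` is
#' interpolated linearly between nodes and assumed to be 1 beyond the table
#' (a warning is issued when the table is shorter than `2R`).
#'
#' @param R observation sphere radius (A), > 0.
#' @param rdf an [rdf_table()].
#' @param rho_w solvent number density (A^-3).
#' @param dr_max maximum quadrature step (A).
#' @return Dimensionless normalized variance.
#' @export
chi_numeric <- function(R, rdf, rho_w, dr_max = 0.01) {
  stopifnot(inherits(rdf, "rdf_table"))
  if (!is.finite(R) || R <= 0) stop("chi_numeric: R must be > 0")
  if (!is.finite(rho_w) || rho_w < 0) stop("chi_numeric: rho_w must be >= 0")
  if (rdf$r_max < 2 * R)
    warning(sprintf(paste0("chi_numeric: RDF table ends at r = %.3g < 2R = %.3g; ",
                           "assuming g = 1 for the missing tail"),
                    rdf$r_max, 2 * R))
  gf <- .g_fun(rdf)
  # quadrature grid: native nodes within [0, 2R] refined to step <= dr_max
  nodes <- unique(sort(c(0, rdf$r[rdf$r < 2 * R], 2 * R)))
  grid <- unlist(lapply(seq_len(length(nodes) - 1L), function(i) {
    k <- max(1L, ceiling((nodes[i + 1L] - nodes[i]) / dr_max))
    seq(nodes[i], nodes[i + 1L], length.out = k + 1L)[-(k + 1L)]
  }))
  grid <- c(grid, 2 * R)
  integrand <- 4 * pi * grid^2 * (gf(grid) - 1) * lens_volume(grid, R)
  V <- (4 * pi / 3) * R^3
  integral <- sum(diff(grid) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  1 + (rho_w / V) * integral
}

#' Occupancy moments from a pair correlation function
#'
#' First and second occupancy moments of a spherical observation volume:
#' `<n> = rho_w V` and `<n^2> = <n> + <n>^2 + rho_w^2 * I` where `I` is the
#' double integral of `(g - 1)` over the volume, evaluated by the same
#' quadrature as [chi_numeric()] so that
#' `chi = (<n^2> - <n>^2)/<n>` is consistent to machine precision.
#'
#' @inheritParams chi_numeric
#' @return An [occupancy_moments()] object.
#' @export
occupancy_moments_from_rdf <- function(R, rdf, rho_w, dr_max = 0.01) {
  ch <- chi_numeric(R, rdf, rho_w, dr_max = dr_max)
  n_mean <- rho_w * (4 * pi / 3) * R^3
  # chi = (var)/<n> and var = <n> + rho^2 I  =>  <n^2> = chi <n> + <n>^2
  occupancy_moments(n_mean = n_mean, n2_mean = ch * n_mean + n_mean^2)
}

#' Brute-force Monte Carlo check of the fluctuation integral
#'
#' Estimates `chi` for a step pair correlation function
#' (`g = 0` below `d_ww`, 1 beyond) by direct Monte Carlo evaluation of the
#' double volume integral: sample independent point pairs uniformly in the
#' sphere and estimate the probability that their separation is below
#' `d_ww`, giving `chi = 1 - rho_w V P(|r1 - r2| < d_ww)`.  This is an
#' independent 6-dimensional oracle for [chi_numeric()]; it shares no code
#' with the quadrature path.
#'
#' @param R sphere radius (A).
#' @param d_ww step diameter (A).
#' @param rho_w number density (A^-3).
#' @param n_samples number of point pairs.
#' @return List with `chi`, `se` (standard error of the estimate) and
#'   `p_hat` (the raw pair-overlap probability).
#' @export
chi_step_mc <- function(R, d_ww, rho_w, n_samples = 1e6) {
  if (R <= 0 || d_ww <= 0 || rho_w < 0) stop("chi_step_mc: invalid inputs")
  n_samples <- as.integer(n_samples)
  hits <- cpp_pair_dist_lt(R, d_ww, n_samples)
  p_hat <- hits / n_samples
  V <- (4 * pi / 3) * R^3
  se_p <- sqrt(max(p_hat * (1 - p_hat), 1 / n_samples)) / sqrt(n_samples)
  list(chi = 1 - rho_w * V * p_hat, se = rho_w * V * se_p, p_hat = p_hat)
}
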