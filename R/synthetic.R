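#' Generate ideal-gas configurations
#'
#' Independent configurations of non-interacting particles: the particle
#' count of each configuration is drawn Poisson(`rho * V`) (so that any
#' subvolume has exactly Poisson occupancy statistics, `chi = 1`), and
#' positions are i.i.d. uniform in the box.  The end-to-end null oracle for
#' the probe-insertion sampler.
#'
#' @param rho number density (A^-3), >= 0.
#' @param box box edge(s) (A), length 1 or 3.
#' @param n_configs number of configurations.
#' @param seed RNG seed.
#' @return List of [particle_configuration()] objects.
#' @export
generate_ideal_gas <- function(rho, box, n_configs = 200L, seed = 1L) {
  if (!is.finite(rho) || rho < 0) stop("generate_ideal_gas: rho must be >= 0")
  if (length(box) == 1L) box <- rep(box, 3)
  V <- prod(box)
  set.seed(seed)
  lapply(seq_len(n_configs), function(i) {
    n <- stats::rpois(1, rho * V)
    xyz <- cbind(stats::runif(n, 0, box[1]),
                 stats::runif(n, 0, box[2]),
                 stats::runif(n, 0, box[3]))
    particle_configuration(xyz, box, periodic = TRUE)
  })
}

#' Hard-sphere fluid configurations by Metropolis Monte Carlo
#'
#' Single-particle displacement Monte Carlo of N hard spheres of diameter 1
#' in a cubic periodic box sized to the requested packing fraction
#' `eta = pi N / (6 L^3)`.  Starts from an fcc lattice; the displacement
#' step is auto-tuned toward the target acceptance during equilibration
#' only, then frozen for production.  Emitted configurations are verified
#' exhaustively to contain no overlapping pair.  This correlated fluid is
#' the desk-scale oracle whose large-volume fluctuations are fixed by the
#' Carnahan-Starling compressibility.
#'
#' @param eta packing fraction, in (0, 0.494) (fluid branch).
#' @param N particle count (<= 2000).
#' @param n_configs configurations to emit.
#' @param n_equil equilibration sweeps (discarded).
#' @param sweeps_between production sweeps between emitted configurations.
#' @param seed RNG seed.
#' @param target_acceptance Metropolis acceptance targeted by the tuner.
#' @return List with `configs` (list of [particle_configuration()]),
#'   `acceptance` (production acceptance ratio), `step` (frozen step, A),
#'   `L` (box edge), `eta`, `rho`.
#' @export
hs_monte_carlo <- function(eta, N = 256L, n_configs = 200L, n_equil = 2000L,
                           sweeps_between = 100L, seed = 1L,
                           target_acceptance = 0.4) {
  if (!is.finite(eta) || eta <= 0 || eta >= 0.494)
    stop("hs_monte_carlo: eta must be in (0, 0.494) (fluid branch)")
  if (N > 2000L) stop("hs_monte_carlo: N capped at 2000 (desk scale)")
  rho <- 6 * eta / pi           # diameter d = 1 sets the length unit
  L <- (N / rho)^(1 / 3)
  set.seed(seed)
  out <- cpp_hs_mc(as.integer(N), L, as.integer(n_configs),
                   as.integer(n_equil), as.integer(sweeps_between),
                   0.3, target_acceptance)
  configs <- lapply(out$configs, function(m)
    particle_configuration(m, rep(L, 3), periodic = TRUE))
  for (cf in configs)
    if (cpp_min_pair_dist(cf$coords, cf$box, cf$periodic) < 1)
      stop("hs_monte_carlo: emitted configuration violates the hard core")
  list(configs = configs, acceptance = out$acceptance, step = out$step,
       L = L, eta = eta, rho = rho)
}

#' Carnahan-Starling reduced compressibility
#'
#' The macroscopic normalized occupancy variance of the hard-sphere fluid:
#' `(1 - eta)^4 / (1 + 4 eta + 4 eta^2 - 4 eta^3 + eta^4)`, the inverse of
#' the Carnahan-Starling `d(beta P)/d(rho)`.  At `eta = 0.30` this is about
#' 0.098.
#'
#' @param eta packing fraction.
#' @return Dimensionless reduced compressibility.
#' @export
carnahan_starling_chi <- function(eta) {
  if (any(eta < 0) || any(eta >= 1)) stop("carnahan_starling_chi: bad eta")
  (1 - eta)^4 / (1 + 4 * eta + 4 * eta^2 - 4 * eta^3 + eta^4)
}
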