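# Common fixtures: ambient-water-like state point and fluctuation model.
ambient_sp <- function() state_point(T = 298.15, rho_w = 0.0334, kappa_T = 4.5e-5)
ambient_model <- function(d_ww = 2.647) chi_model(ambient_sp(), d_ww)

# Random physically plausible state points for property-style loops.
random_state_points <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(T = runif(n, 250, 650),
             rho = runif(n, 0.005, 0.05),
             kappa = 10^runif(n, -5, -3),
             d = runif(n, 2, 3.5))
}

# Step pair correlation function: 0 below d, 1 beyond, on a dense grid.
step_rdf <- function(d, r_max = 30) {
  eps <- 1e-9
  rdf_table(c(0, d - eps, d, r_max), c(0, 0, 1, 1))
}
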