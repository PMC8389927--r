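#' Particle configuration in a (periodic) box
#'
#' @param coords numeric matrix with 3 columns (A); may have zero rows.
#' @param box three positive edge lengths (A).
#' @param periodic logical, length 1 or 3: periodicity per axis.
#' @return Object of class `particle_configuration`; coordinates on
#'   periodic axes are wrapped into `[0, box)`.
#' @export
particle_configuration <- function(coords, box, periodic = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0 && ncol(coords) != 3L)
    stop("particle_configuration: coords must have 3 columns")
  if (nrow(coords) == 0L) coords <- matrix(numeric(0), 0, 3)
  if (length(box) == 1L) box <- rep(box, 3)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("particle_configuration: box must be 3 positive edge lengths")
  if (length(periodic) == 1L) periodic <- rep(periodic, 3)
  storage.mode(coords) <- "double"
  for (k in 1:3) if (periodic[k] && nrow(coords) > 0)
    coords[, k] <- coords[, k] - box[k] * floor(coords[, k] / box[k])
  structure(list(coords = coords, box = as.numeric(box),
                 periodic = as.logical(periodic)),
            class = "particle_configuration")
}

#' @export
print.particle_configuration <- function(x, ...) {
  cat(sprintf("particle_configuration: %d particles, box %.3g x %.3g x %.3g A\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Observation-volume probe specification
#'
#' Spheres are used for bulk solute-sized volumes; thin `L x L x width`
#' cuboids probe fluctuations at a set distance (`z_center`) from a surface.
#'
#' @param shape `"sphere"` or `"cuboid"`.
#' @param R sphere radius (A); required for spheres.
#' @param L cuboid edge (A); required for cuboids.
#' @param width fixed cuboid dimension along z (A), default 3.
#' @param z_center optional z coordinate of the cuboid center (A); when
#'   absent, insertion centers are fully random.
#' @param n_insertions random insertions per configuration.
#' @param seed RNG seed recorded with the probe and applied by
#'   [sample_occupancy()].
#' @return Object of class `probe_spec`.
#' @export
probe_spec <- function(shape = c("sphere", "cuboid"), R = NULL, L = NULL,
                       width = 3, z_center = NULL, n_insertions = 2000L,
                       seed = 1L) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (is.null(R) || !is.finite(R) || R <= 0)
      stop("probe_spec: sphere requires R > 0")
  } else {
    if (is.null(L) || !is.finite(L) || L <= 0)
      stop("probe_spec: cuboid requires L > 0")
    if (!is.finite(width) || width <= 0) stop("probe_spec: width must be > 0")
  }
  if (n_insertions < 1L) stop("probe_spec: n_insertions must be >= 1")
  structure(list(shape = shape, R = R, L = L, width = width,
                 z_center = z_center,
                 n_insertions = as.integer(n_insertions),
                 seed = as.integer(seed)),
            class = "probe_spec")
}

# Internal: shape code / dims for the C++ counter, plus a geometry check.
.probe_geometry <- function(config, probe) {
  if (probe$shape == "sphere") {
    ext <- rep(2 * probe$R, 3)
    list(shape = 0L, R = probe$R, dims = c(0, 0, 0), ext = ext)
  } else {
    ext <- c(probe$L, probe$L, probe$width)
    list(shape = 1L, R = 0, dims = ext, ext = ext)
  }
}

#' Count solvent centers inside a probe volume
#'
#' Membership uses the minimum-image convention on periodic axes; spheres
#' use strict `<` on the distance, cuboids half-open `[lo, hi)` intervals,
#' so boundary particles are counted reproducibly.
#'
#' @param config a [particle_configuration()].
#' @param center numeric length-3 probe center (A).
#' @param probe a [probe_spec()].
#' @return Integer occupancy.
#' @export
count_occupancy <- function(config, center, probe) {
  stopifnot(inherits(config, "particle_configuration"),
            inherits(probe, "probe_spec"))
  if (length(center) != 3L || any(!is.finite(center)))
    stop("count_occupancy: center must be 3 finite coordinates")
  g <- .probe_geometry(config, probe)
  bad <- config$periodic & (g$ext > config$box)
  if (any(bad))
    stop("count_occupancy: probe extent exceeds a periodic box edge")
  cpp_count_occupancy(config$coords, config$box, config$periodic,
                      as.numeric(center), g$shape, g$R, g$dims)
}

#' Sample occupancy statistics by random probe insertion
#'
#' Performs `probe$n_insertions` uniform random insertions in each
#' configuration (Widom-style test volumes; for cuboids with a `z_center`,
#' only x and y are randomized), accumulates the occupancy histogram and
#' estimates `<n>`, `<n^2>` and the normalized variance
#' `chi = (<n^2> - <n>^2)/<n>`.  Standard errors come from a block
#' bootstrap over whole configurations, since insertions within one
#' configuration are correlated.  Fully deterministic for a fixed
#' `probe$seed`.
#'
#' @param configs a list of [particle_configuration()] objects (or one).
#' @param probe a [probe_spec()].
#' @param n_boot bootstrap resamples over configurations (default 200).
#' @return Object of class `occupancy_histogram`: `counts` (named by n),
#'   `p`, `n_insertions_total`, `n_mean`, `n2_mean`, `chi`, standard errors
#'   `se_n_mean`, `se_chi`, and `seed`.
#' @export
sample_occupancy <- function(configs, probe, n_boot = 200L) {
  if (inherits(configs, "particle_configuration")) configs <- list(configs)
  stopifnot(length(configs) >= 1L, inherits(probe, "probe_spec"))
  g <- .probe_geometry(configs[[1]], probe)
  fixed_z <- probe$shape == "cuboid" && !is.null(probe$z_center)
  zc <- if (fixed_z) probe$z_center else 0
  set.seed(probe$seed)
  per_config <- lapply(configs, function(cf) {
    stopifnot(inherits(cf, "particle_configuration"))
    bad <- cf$periodic & (g$ext > cf$box)
    if (any(bad)) stop("sample_occupancy: probe exceeds a periodic box edge")
    cpp_sample_config(cf$coords, cf$box, cf$periodic, g$shape, g$R, g$dims,
                      probe$n_insertions, fixed_z, zc)
  })
  all_counts <- unlist(per_config)
  total <- length(all_counts)
  tab <- tabulate(all_counts + 1L)
  names(tab) <- as.character(seq_along(tab) - 1L)
  p <- tab / total
  m1 <- mean(all_counts)
  m2 <- mean(as.numeric(all_counts)^2)
  chi_hat <- if (m1 > 0) (m2 - m1^2) / m1 else NA_real_

  # block bootstrap over configurations
  nc <- length(per_config)
  cfg_m1 <- vapply(per_config, mean, numeric(1))
  cfg_m2 <- vapply(per_config, function(v) mean(as.numeric(v)^2), numeric(1))
  if (nc > 1L && n_boot > 0L) {
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nc, nc, replace = TRUE)
      b1 <- mean(cfg_m1[idx]); b2 <- mean(cfg_m2[idx])
      c(b1, if (b1 > 0) (b2 - b1^2) / b1 else NA_real_)
    }, numeric(2))
    se_m1 <- sd(boot[1, ])
    se_chi <- sd(boot[2, ], na.rm = TRUE)
  } else {
    se_m1 <- NA_real_; se_chi <- NA_real_
  }
  structure(list(counts = tab, p = p, n_insertions_total = total,
                 n_mean = m1, n2_mean = m2, chi = chi_hat,
                 se_n_mean = se_m1, se_chi = se_chi, seed = probe$seed),
            class = "occupancy_histogram")
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf(paste0("occupancy_histogram: %d insertions, <n> = %.4g (se %.2g), ",
                     "chi = %.4g (se %.2g)\n"),
              x$n_insertions_total, x$n_mean, x$se_n_mean, x$chi, x$se_chi))
  invisible(x)
}

#' Closed-ensemble finite-size correction for sampled variances
#'
#' Configurations with a fixed particle number suppress the occupancy
#' variance of a subvolume `v` of the box `V`: the pair correlation
#' function carries the well-known canonical offset `-chi_inf / N`, which
#' shifts the sampled normalized variance by `-(v/V) * chi_inf` (for an
#' ideal gas at fixed N this reproduces the exact binomial result
#' `chi = 1 - v/V`).  Adding the offset back recovers the open-system
#' value, given an estimate of the macroscopic limit `chi_inf`.
#'
#' @param chi_sampled normalized variance sampled from fixed-N configurations.
#' @param v probe volume (A^3).
#' @param V box volume (A^3).
#' @param chi_inf macroscopic normalized variance used for the offset.
#' @return Corrected open-system `chi` estimate.
#' @seealso [chi_infinity_from_configs()] for the self-consistent
#'   extrapolation that estimates `chi_inf` itself.
#' @export
closed_system_correction <- function(chi_sampled, v, V, chi_inf) {
  if (v <= 0 || V <= 0 || v >= V)
    stop("closed_system_correction: need 0 < v < V")
  chi_sampled + (v / V) * chi_inf
}

#' Estimate the macroscopic normalized variance from configurations
#'
#' Samples the normalized occupancy variance for spheres on a radius grid
#' and extrapolates to infinite volume.  In a closed fixed-N box the
#' sampled variance follows
#' `chi(R) = chi_inf * (1 - v/V) + s1/R + s3/R^3` at large R, combining
#' the cubic-in-1/R approach to the macroscopic limit with the canonical
#' finite-size offset `-(v/V) chi_inf`; a weighted least-squares fit of
#' the sampled values onto the basis `{1 - v/V, 1/R, 1/R^3}` (no
#' intercept) yields `chi_inf` as the leading coefficient, in the spirit
#' of finite-volume Kirkwood-Buff extrapolation.
#'
#' @param configs list of [particle_configuration()] objects sharing one box.
#' @param R_grid sphere radii (A); default 8 radii from `R_min` to 96% of
#'   the half-box.
#' @param R_min smallest radius (A) when `R_grid` is defaulted.
#' @param n_insertions insertions per configuration per radius.
#' @param seed base RNG seed (radius i uses `seed + i`).
#' @return List with `chi_inf`, `se` (from the weighted fit), `fit` (the
#'   `lm` object) and `samples` (data.frame of R, chi, se_chi).
#' @export
chi_infinity_from_configs <- function(configs, R_grid = NULL, R_min = 1.5,
                                      n_insertions = 2000L, seed = 1L) {
  stopifnot(length(configs) >= 2L)
  box <- configs[[1]]$box
  V <- prod(box)
  if (is.null(R_grid))
    R_grid <- seq(R_min, 0.48 * min(box), length.out = 8L)
  samples <- do.call(rbind, lapply(seq_along(R_grid), function(i) {
    h <- sample_occupancy(configs, probe_spec("sphere", R = R_grid[i],
                                              n_insertions = n_insertions,
                                              seed = seed + i))
    data.frame(R = R_grid[i], chi = h$chi, se_chi = h$se_chi)
  }))
  b0 <- 1 - (4 * pi / 3) * samples$R^3 / V
  x1 <- 1 / samples$R
  x3 <- x1^3
  fit <- lm(samples$chi ~ 0 + b0 + x1 + x3, weights = 1 / samples$se_chi^2)
  list(chi_inf = unname(coef(fit)[1]),
       se = sqrt(stats::vcov(fit)[1, 1]),
       fit = fit, samples = samples)
}

#' Normalized-variance profile for cuboidal probes
#'
#' Computes `chi(L; z)` for every combination of cuboid edge `L` and center
#' height `z`, the quantity used to characterize fluctuations at increasing
#' distances from a surface (surface normal along z by convention).
#'
#' @param configs list of [particle_configuration()] objects.
#' @param L_list cuboid edges (A).
#' @param z_list cuboid center heights (A); use `NULL` entries for fully
#'   random placement.
#' @param width fixed cuboid dimension (A), default 3.
#' @param n_insertions insertions per configuration per (L, z).
#' @param seed base RNG seed; each (L, z) pair uses `seed + index`.
#' @return `data.frame` with columns `L`, `z`, `n_mean`, `chi`, `se_chi`.
#' @export
chi_profile <- function(configs, L_list, z_list, width = 3,
                        n_insertions = 2000L, seed = 1L) {
  grid <- expand.grid(L = L_list, z = if (is.null(z_list)) NA else z_list)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    zc <- if (is.na(grid$z[i])) NULL else grid$z[i]
    pr <- probe_spec("cuboid", L = grid$L[i], width = width, z_center = zc,
                     n_insertions = n_insertions, seed = seed + i)
    h <- sample_occupancy(configs, pr)
    data.frame(L = grid$L[i], z = grid$z[i], n_mean = h$n_mean,
               chi = h$chi, se_chi = h$se_chi)
  })
  do.call(rbind, res)
}

#' Read particle configurations from an XYZ file
#'
#' Extended XYZ text: per frame an atom count line, a comment line whose
#' first three numeric fields are the box edges `Lx Ly Lz` in Angstrom,
#' then `name x y z` lines (coordinates in A).  All species are read;
#' filter with `species` to select one.
#'
#' @param path file path.
#' @param species optional atom-name filter (e.g. `"O"`).
#' @param periodic periodicity flags for the returned configurations.
#' @return List of [particle_configuration()] objects.
#' @export
read_xyz <- function(path, species = NULL, periodic = TRUE) {
  if (!file.exists(path)) stop("read_xyz: file not found: ", path)
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("read_xyz: expected atom count at line ", i)
    box <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 1L]), "\\s+")[[1]][1:3]))
    if (any(is.na(box))) stop("read_xyz: comment line must hold box edges")
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    nm <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!is.null(species)) xyz <- xyz[nm == species, , drop = FALSE]
    configs[[length(configs) + 1L]] <-
      particle_configuration(xyz, box, periodic)
    i <- i + 2L + nat
  }
  configs
}

#' Write particle configurations to an XYZ file
#'
#' @param configs list of [particle_configuration()] objects (or one).
#' @param path output path.
#' @param name atom name to write.
#' @export
write_xyz <- function(configs, path, name = "X") {
  if (inherits(configs, "particle_configuration")) configs <- list(configs)
  con <- file(path, "w"); on.exit(close(con))
  for (cf in configs) {
    writeLines(as.character(nrow(cf$coords)), con)
    writeLines(sprintf("%.8g %.8g %.8g", cf$box[1], cf$box[2], cf$box[3]), con)
    if (nrow(cf$coords) > 0)
      writeLines(sprintf("%s %.8f %.8f %.8f", name,
                         cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Fixed-column GROMACS text format, one frame: title, atom count, atom
#' lines (positions in nm, converted to Angstrom by a factor of 10), box
#' vector line (first three fields = rectangular edges, nm).
#'
#' @param path file path.
#' @param species optional atom-name filter (e.g. `"OW"`).
#' @param periodic periodicity flags.
#' @return A [particle_configuration()] with coordinates in Angstrom.
#' @export
read_gro <- function(path, species = NULL, periodic = TRUE) {
  if (!file.exists(path)) stop("read_gro: file not found: ", path)
  lines <- readLines(path)
  nat <- as.integer(trimws(lines[2]))
  atom_lines <- lines[3:(2 + nat)]
  nm <- trimws(substr(atom_lines, 11, 15))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]][1:3])
  keep <- if (is.null(species)) rep(TRUE, nat) else nm == species
  particle_configuration(cbind(x, y, z)[keep, , drop = FALSE] * 10,
                         box * 10, periodic)
}
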