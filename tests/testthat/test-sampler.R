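test_that("occupancy counting matches exhaustive image enumeration", {
  # 3x3x3 unit lattice in a 3^3 periodic box, sphere R = 1.1 at a node
  pts <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  cfg <- particle_configuration(pts, box = 3, periodic = TRUE)
  probe <- probe_spec("sphere", R = 1.1, n_insertions = 1)
  center <- c(1, 1, 1)
  # brute force over all 27 periodic images of every particle
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 3
  brute <- 0L
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(shifts) + pts[i, ] - center)^2)
    if (min(d2) < 1.1^2) brute <- brute + 1L
  }
  expect_identical(count_occupancy(cfg, center, probe), brute)
  expect_identical(brute, 7L)  # node + 6 nearest neighbours at distance 1
})

test_that("counting handles empty and singleton configurations", {
  empty <- particle_configuration(matrix(numeric(0), 0, 3), box = 10)
  probe <- probe_spec("sphere", R = 2)
  expect_identical(count_occupancy(empty, c(5, 5, 5), probe), 0L)
  one <- particle_configuration(matrix(c(5, 5, 5), 1), box = 10)
  expect_identical(count_occupancy(one, c(5, 5, 5), probe), 1L)
  cub <- probe_spec("cuboid", L = 4, width = 2)
  expect_identical(count_occupancy(one, c(5, 5, 5), cub), 1L)
  # half-open cuboid boundary: particle exactly at +L/2 is out, at -L/2 is in
  expect_identical(count_occupancy(one, c(3, 5, 5), cub), 0L)  # x = +2 edge
  expect_identical(count_occupancy(one, c(7, 5, 5), cub), 1L)  # x = -2 edge
})

test_that("counting is invariant under lattice-vector shifts", {
  set.seed(5)
  coords <- matrix(runif(90, 0, 8), ncol = 3)
  cfg <- particle_configuration(coords, box = 8)
  probe <- probe_spec("sphere", R = 2.5)
  base <- count_occupancy(cfg, c(1, 7, 4), probe)
  for (shift in list(c(8, 0, 0), c(0, -8, 8), c(16, 8, -8))) {
    cfg2 <- particle_configuration(sweep(coords, 2, shift, "+"), box = 8)
    expect_identical(count_occupancy(cfg2, c(1, 7, 4), probe), base)
  }
})

test_that("probes larger than the periodic box are rejected", {
  cfg <- particle_configuration(matrix(runif(30), 10, 3), box = 5)
  expect_error(count_occupancy(cfg, c(2, 2, 2), probe_spec("sphere", R = 3)),
               "exceeds")
  expect_error(sample_occupancy(list(cfg), probe_spec("cuboid", L = 6)),
               "exceeds")
})

test_that("sampling is bit-reproducible for a fixed seed", {
  cfgs <- generate_ideal_gas(0.02, 10, n_configs = 3, seed = 9)
  probe <- probe_spec("sphere", R = 2, n_insertions = 50, seed = 123)
  h1 <- sample_occupancy(cfgs, probe)
  h2 <- sample_occupancy(cfgs, probe)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$n_mean, h2$n_mean)
  h3 <- sample_occupancy(cfgs, probe_spec("sphere", R = 2, n_insertions = 50,
                                          seed = 124))
  expect_false(identical(h1$counts, h3$counts))
})

test_that("histogram moments are consistent with the histogram itself", {
  cfgs <- generate_ideal_gas(0.0334, 12, n_configs = 10, seed = 2)
  h <- sample_occupancy(cfgs, probe_spec("sphere", R = 3, n_insertions = 200,
                                         seed = 4))
  n <- as.integer(names(h$counts))
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(sum(n * h$p), h$n_mean, tolerance = 1e-12)
  expect_equal(sum(n^2 * h$p), h$n2_mean, tolerance = 1e-12)
})

test_that("ideal-gas sampling recovers Poisson statistics", {
  cfgs <- generate_ideal_gas(0.0334, 15, n_configs = 60, seed = 21)
  h <- sample_occupancy(cfgs, probe_spec("sphere", R = 3, n_insertions = 800,
                                         seed = 22))
  n_true <- 0.0334 * (4 * pi / 3) * 27
  expect_lt(abs(h$n_mean - n_true), 3 * h$se_n_mean)
  expect_lt(abs(h$chi - 1), 3 * h$se_chi)
  hc <- sample_occupancy(cfgs, probe_spec("cuboid", L = 5, width = 3,
                                          n_insertions = 800, seed = 23))
  expect_lt(abs(hc$n_mean - 0.0334 * 75), 3 * hc$se_n_mean)
  expect_lt(abs(hc$chi - 1), 3 * hc$se_chi)
})

test_that("estimator error shrinks with more insertions", {
  cfgs <- generate_ideal_gas(0.0334, 15, n_configs = 40, seed = 31)
  h_small <- sample_occupancy(cfgs, probe_spec("sphere", R = 3,
                                               n_insertions = 100, seed = 5))
  h_big <- sample_occupancy(cfgs, probe_spec("sphere", R = 3,
                                             n_insertions = 4000, seed = 5))
  expect_lt(h_big$se_n_mean, h_small$se_n_mean)
})

test_that("cuboid chi profile of a homogeneous gas is flat at one", {
  cfgs <- generate_ideal_gas(0.04, 14, n_configs = 40, seed = 41)
  prof <- chi_profile(cfgs, L_list = c(1, 4, 7), z_list = c(3, 7, 11),
                      width = 3, n_insertions = 600, seed = 42)
  expect_equal(nrow(prof), 9L)
  for (i in seq_len(nrow(prof)))
    expect_lt(abs(prof$chi[i] - 1), 4 * prof$se_chi[i])
  # small-volume limit: chi -> 1 tightly
  tiny <- chi_profile(cfgs, L_list = 0.8, z_list = 7, width = 0.8,
                      n_insertions = 600, seed = 43)
  expect_lt(abs(tiny$chi - 1), 4 * tiny$se_chi)
})

test_that("XYZ configurations round-trip through files", {
  cfgs <- generate_ideal_gas(0.01, 9, n_configs = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cfgs, path)
  back <- read_xyz(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$box, cfgs[[i]]$box)
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("GRO reader parses fixed columns and converts nm to Angstrom", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "synthetic two-water fixture",
    "    4",
    "    1SOL     OW    1   0.230   0.628   0.113",
    "    1SOL    HW1    2   0.260   0.693   0.177",
    "    2SOL     OW    3   1.113   1.130   0.150",
    "    2SOL    HW2    4   1.150   1.200   0.200",
    "   1.86206   1.86206   1.86206"), path)
  cfg <- read_gro(path, species = "OW")
  expect_equal(nrow(cfg$coords), 2L)
  expect_equal(cfg$box, rep(18.6206, 3))
  expect_equal(cfg$coords[1, ], c(2.30, 6.28, 1.13), ignore_attr = TRUE)
  all4 <- read_gro(path)
  expect_equal(nrow(all4$coords), 4L)
})
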