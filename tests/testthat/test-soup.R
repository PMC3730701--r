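test_that("initialisation draws the documented ensemble", {
  cfg <- ensemble_config(n_subsystems = 128, seed = 11)
  st <- init_ensemble(cfg)
  expect_equal(sum(st$closed_mask), 43)  # round(128/3)
  expect_true(all(st$kappa > 0 & st$kappa <= 1))
  expect_equal(dim(st$positions), c(128, 2))
  expect_equal(dim(st$chem), c(128, 3))

  # seeded determinism: bit-identical states
  st2 <- init_ensemble(cfg)
  expect_identical(st, st2)

  # degenerate single-subsystem ensemble
  st1 <- init_ensemble(ensemble_config(n_subsystems = 1, seed = 2))
  expect_equal(nrow(st1$positions), 1)
  expect_equal(sum(st1$closed_mask), 0)  # round(1/3) = 0
})

test_that("contact adjacency follows the column (influence-from) convention", {
  pos <- rbind(c(0, 0), c(2, 0))
  expect_true(all(contact_neighbors(pos, 1) == 0))

  pos <- rbind(c(0, 0), c(0.5, 0))
  A <- contact_neighbors(pos, 1)
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 1], 1)
  expect_equal(diag(A), c(0, 0))

  # closing subsystem 2 zeroes its column but not its row
  A <- contact_neighbors(pos, 1, closed_mask = c(FALSE, TRUE))
  expect_equal(A[1, 2], 0)
  expect_equal(A[2, 1], 1)
})

test_that("local average includes self and ignores closed neighbours", {
  chem <- rbind(c(1, 2, 3), c(5, 6, 7), c(100, 100, 100))
  pos <- rbind(c(0, 0), c(0.5, 0), c(10, 10))  # 3 isolated
  A <- contact_neighbors(pos, 1)
  expect_equal(local_average(chem, A, 3), c(100, 100, 100))
  expect_equal(local_average(chem, A, 1), c(3, 4, 5))  # mean of rows 1, 2

  # a closed neighbour's states cannot enter the average
  A2 <- contact_neighbors(pos, 1, closed_mask = c(FALSE, TRUE, FALSE))
  before <- local_average(chem, A2, 1)
  chem2 <- chem
  chem2[2, ] <- c(-999, 999, 0)
  expect_equal(local_average(chem2, A2, 1), before)
})

test_that("electrochemical flow has the Lorenz fixed point and structure", {
  cfg <- ensemble_config(n_subsystems = 5, seed = 3)
  st <- init_ensemble(cfg)
  A <- contact_neighbors(st$positions, cfg$coupling_radius, st$closed_mask)

  # all-zero electrochemical states are a fixed point for any topology
  st0 <- st
  st0$chem[] <- 0
  expect_true(all(electrochemical_flow(st0, A) == 0))

  # kappa multiplies the flow
  f1 <- electrochemical_flow(st, A)
  st2 <- st
  st2$kappa <- 2 * st$kappa
  expect_equal(electrochemical_flow(st2, A), 2 * f1)

  # isolated subsystem with kappa = 1: textbook Lorenz right-hand side
  stl <- init_ensemble(ensemble_config(n_subsystems = 1, seed = 4))
  stl$kappa <- 1
  x <- drop(stl$chem)
  flow <- drop(electrochemical_flow(stl, matrix(0, 1, 1)))
  expect_equal(flow, c(10 * (x[2] - x[1]),
                       x[1] * (32 - x[3]) - x[2],
                       x[1] * x[2] - 8 / 3 * x[3]))
})

test_that("pairwise forces obey Newton's third law and the inverse-square law", {
  fp <- list(repulsion_strength = 1.3, attraction_strength = 2,
             viscosity_coeff = 0, well_stiffness = 0)
  st <- list(positions = rbind(c(0, 0), c(0.4, 0.3)),
             velocities = matrix(0, 2, 2),
             chem = rbind(c(0, 0, 5), c(0, 0, 5)),  # coherent third states
             kappa = c(1, 1), closed_mask = c(FALSE, FALSE), time = 0)
  class(st) <- "ensemble_state"
  acc <- newtonian_acceleration(st, fp)
  expect_equal(acc[1, ], -acc[2, ])

  # a lone subsystem at rest at the origin feels nothing
  st1 <- st
  st1$positions <- matrix(0, 1, 2)
  st1$velocities <- matrix(0, 1, 2)
  st1$chem <- matrix(0, 1, 3)
  st1$closed_mask <- FALSE
  expect_equal(newtonian_acceleration(st1,
    utils::modifyList(fp, list(well_stiffness = 0.5))), matrix(0, 1, 2))

  # halving a small separation quadruples the repulsion (near field, where
  # the screening factor is ~1)
  frep <- function(r) {
    s <- st
    s$positions <- rbind(c(0, 0), c(r, 0))
    s$chem[] <- 0  # neutral coherence irrelevant with attraction off
    a <- newtonian_acceleration(
      s, utils::modifyList(fp, list(attraction_strength = 0)))
    abs(a[1, 1])
  }
  expect_equal(frep(0.05) / frep(0.1), 4, tolerance = 0.005)

  # no bond forms with a functionally closed partner (pure repulsion),
  # but the force stays equal and opposite
  stc <- st
  stc$closed_mask <- c(FALSE, TRUE)
  accc <- newtonian_acceleration(stc, fp)
  expect_equal(accc[1, ], -accc[2, ])
  expect_gt(sum(accc[2, ] * c(0.4, 0.3)), 0)  # net repulsion along the axis
})

test_that("a noise-free step leaves a force-free fixed point unchanged", {
  cfg <- ensemble_config(n_subsystems = 3, noise_sd = 0, seed = 5,
                         force_params = list(repulsion_strength = 0,
                                             attraction_strength = 0,
                                             viscosity_coeff = 0,
                                             well_stiffness = 0))
  st <- init_ensemble(cfg)
  st$velocities[] <- 0
  st$chem[] <- 0
  st2 <- step(st, cfg)
  expect_equal(st2$positions, st$positions)
  expect_equal(st2$velocities, st$velocities)
  expect_equal(st2$chem, st$chem)
  expect_equal(st2$time, st$time + cfg$dt)
})

test_that("an uncoupled noise-free subsystem follows the Lorenz oracle", {
  cfg <- ensemble_config(n_subsystems = 1, duration = 2, noise_sd = 0,
                         closed_fraction = 0, seed = 6)
  traj <- simulate_soup(cfg)
  ref <- reference_lorenz(traj$chem[1, 1, ], dt = cfg$dt,
                          n_steps = round(2 / cfg$dt), kappa = traj$kappa[1])
  ref_saved <- ref[seq(1, nrow(ref), by = round(1 / cfg$dt)), ]
  expect_equal(matrix(traj$chem[, 1, ], ncol = 3), ref_saved,
               tolerance = 1e-8)
})

test_that("the uncoupled limit reduces every subsystem to independent Lorenz",
{
  cfg <- ensemble_config(n_subsystems = 3, duration = 1, noise_sd = 0,
                         coupling_radius = 1e-9, closed_fraction = 0,
                         seed = 7,
                         force_params = list(repulsion_strength = 0,
                                             attraction_strength = 0,
                                             viscosity_coeff = 0,
                                             well_stiffness = 0))
  traj <- simulate_soup(cfg)
  for (i in 1:3) {
    ref <- reference_lorenz(traj$chem[1, i, ], dt = cfg$dt,
                            n_steps = round(1 / cfg$dt),
                            kappa = traj$kappa[i])
    expect_equal(traj$chem[2, i, ], ref[nrow(ref), ], tolerance = 1e-8)
  }
})

test_that("momentum is conserved without well, viscosity and noise", {
  cfg <- ensemble_config(n_subsystems = 8, duration = 10, noise_sd = 0,
                         seed = 8,
                         force_params = list(repulsion_strength = 1,
                                             attraction_strength = 2,
                                             viscosity_coeff = 0,
                                             well_stiffness = 0))
  traj <- simulate_soup(cfg)
  p0 <- colSums(matrix(traj$velocities[1, , ], 8))
  p1 <- colSums(matrix(traj$velocities[11, , ], 8))
  expect_equal(p1, p0, tolerance = 1e-9)
})

test_that("mechanical energy is non-increasing with viscosity and no noise", {
  fp <- list(repulsion_strength = 1, attraction_strength = 0,
             viscosity_coeff = 1, well_stiffness = 0.25)
  cfg <- ensemble_config(n_subsystems = 6, duration = 4, noise_sd = 0,
                         seed = 9, force_params = fp)
  traj <- simulate_soup(cfg)
  # pair potential of the screened inverse-square repulsion by quadrature
  pair_potential <- function(r) {
    vapply(r, function(ri) stats::integrate(
      function(s) fp$repulsion_strength / s^2 * exp(-s^2 / 8),
      ri, 20)$value, numeric(1))
  }
  energy <- vapply(seq_along(traj$times), function(f) {
    p <- matrix(traj$positions[f, , ], 6)
    v <- matrix(traj$velocities[f, , ], 6)
    D <- as.matrix(dist(p))
    kin <- 0.5 * sum(v^2)
    well <- 0.5 * fp$well_stiffness * sum(p^2)
    pair <- sum(pair_potential(D[upper.tri(D)]))
    kin + well + pair
  }, numeric(1))
  expect_true(all(diff(energy) < 1e-6))
})

test_that("simulation frame bookkeeping and determinism hold", {
  cfg <- ensemble_config(n_subsystems = 4, duration = 4, seed = 10)
  traj <- simulate_soup(cfg)
  expect_equal(length(traj$times), 5)
  expect_equal(diff(traj$times), rep(1, 4))

  traj0 <- simulate_soup(ensemble_config(n_subsystems = 4, duration = 0,
                                         seed = 10))
  expect_equal(length(traj0$times), 1)

  traj2 <- simulate_soup(cfg)
  expect_identical(traj, traj2)
})

test_that("integration blow-up is reported with time and subsystem", {
  cfg <- ensemble_config(n_subsystems = 2, duration = 1, noise_sd = 0,
                         seed = 12, lorenz_params = c(10, 1e154, 8 / 3))
  expect_error(simulate_soup(cfg), "blow-up")
})
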