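test_that("the Lennard-Jones term has its textbook nodes and minimum", {
  lj <- lj_params("Ar", epsilon = 1, sigma = 3)
  pair_at <- function(r) {
    geometry(c("Ar", "Ar"), rbind(c(0, 0, 0), c(r, 0, 0)),
             molecule = c(1, 2))
  }
  expect_equal(lj_energy(pair_at(3), lj), 0, tolerance = 1e-12)
  expect_equal(lj_energy(pair_at(2^(1 / 6) * 3), lj), -1, tolerance = 1e-12)
  expect_equal(lj_energy(pair_at(13), lj, cutoff = 12), 0)
  ## intramolecular pairs are excluded
  same <- geometry(c("Ar", "Ar"), rbind(c(0, 0, 0), c(3.2, 0, 0)))
  expect_equal(lj_energy(same, lj), 0)
  expect_error(lj_energy(pair_at(3), lj_params("Kr", 1, 3)), "Kr|Ar")
  ## mixed types use Lorentz-Berthelot combining
  lj2 <- lj_params(c("Ar", "Ne"), epsilon = c(1, 4), sigma = c(3, 1))
  mix <- geometry(c("Ar", "Ne"), rbind(c(0, 0, 0), c(2^(1 / 6) * 2, 0, 0)),
                  molecule = c(1, 2))
  expect_equal(lj_energy(mix, lj2), -2, tolerance = 1e-12)  # eps=2, sig=2
})

test_that("total energy decomposes additively and respects molecule count", {
  fx <- get_small_bundle()
  lj <- test_lj_table()
  ff <- flexible_forcefield(fx$bundle, lj = lj, lprime = 1, cutoff = 12)
  ## isolated monomer: intramolecular energy only
  mono <- sample_pool(fx$spec, 1, 0.6, seed = 61)[[1]]
  e1 <- total_energy(mono, ff)
  expect_equal(e1$electrostatic, 0)
  expect_equal(e1$lj, 0)
  expect_equal(e1$total, e1$intra)
  ## dimer at huge separation: sum of two monomer energies
  far <- make_surrogate_dimer(fx$spec, 62, offset = c(40, 0, 0))
  m1 <- geometry(far$elements[1:6], far$coords[1:6, ])
  m2 <- geometry(far$elements[7:12], far$coords[7:12, ])
  e_far <- total_energy(far, ff)
  expect_equal(e_far$total,
               total_energy(m1, ff)$total + total_energy(m2, ff)$total,
               tolerance = 1e-9)
  ## interacting dimer: the decomposition sums to the total, and the terms
  ## match an independently assembled sum
  d <- make_surrogate_dimer(fx$spec, 63)
  e <- total_energy(d, ff)
  expect_equal(e$total, e$intra + e$electrostatic + e$lj,
               tolerance = 1e-10 * max(1, abs(e$total)))
  views <- gprff:::molecule_views(d)
  elec_hand <- intermolecular_energy(
    d, gprff:::predicted_global_moments(d, ff, views), 1, 12)
  expect_equal(e$electrostatic, elec_hand, tolerance = 1e-10)
  expect_equal(e$lj, lj_energy(d, lj, 12), tolerance = 1e-12)
})

test_that("rigid motions leave the total energy unchanged", {
  fx <- get_small_bundle()
  ff <- flexible_forcefield(fx$bundle, lj = test_lj_table(), lprime = 1)
  d <- make_surrogate_dimer(fx$spec, 64)
  e0 <- total_energy(d, ff)$total
  e_shift <- total_energy(rigid_move(d, diag(3), c(4, -7, 2)), ff)$total
  expect_lt(abs(e_shift - e0), 1e-9)
  e_rot <- total_energy(rigid_move(d, random_rotation(3)), ff)$total
  expect_lt(abs(e_rot - e0), 1e-8)
})

test_that("static-moment mode agrees with frozen flexible predictions", {
  fx <- get_small_bundle()
  lj <- test_lj_table()
  ff_flex <- flexible_forcefield(fx$bundle, lj = lj, lprime = 1)
  d <- make_surrogate_dimer(fx$spec, 65, temperature = 0)
  ## freeze the flexible model's local moments at this (equilibrium) geometry
  views <- gprff:::molecule_views(d)
  feats <- compute_features(views[[1]]$geom)
  mom <- matrix(0, 6, 25, dimnames = list(NULL, moment_labels()))
  for (col in names(fx$bundle$moment_models)) {
    mom[, col] <- vapply(1:6, function(a) {
      gpr_predict(fx$bundle$moment_models[[col]][[a]], feats[[a]]$values)
    }, numeric(1))
  }
  e_mono <- total_energy(views[[1]]$geom, ff_flex)$total
  ff_stat <- static_forcefield(multipole_set(mom, "local"), e_mono,
                               lj = lj, lprime = 1)
  e_f <- total_energy(d, ff_flex)
  e_s <- total_energy(d, ff_stat)
  ## both monomers sit at the same reference geometry, so the static and
  ## flexible intermolecular terms coincide there
  expect_equal(e_s$electrostatic, e_f$electrostatic, tolerance = 1e-8)
  expect_equal(e_s$lj, e_f$lj, tolerance = 1e-12)
})

test_that("analytic intramolecular forces are exact rigid-motion residuals", {
  fx <- get_small_bundle()
  ff <- flexible_forcefield(fx$bundle, lj = NULL, lprime = 0)
  mono <- sample_pool(fx$spec, 1, 0.8, seed = 66)[[1]]
  F <- forces(mono, ff)
  ## net force vanishes by translation invariance of the features
  expect_lt(max(abs(colSums(F))), 1e-8)
  ## net torque about the centroid vanishes by rotation invariance
  cen <- colMeans(mono$coords)
  tq <- colSums(t(vapply(1:6, function(a) {
    pracma::cross(mono$coords[a, ] - cen, F[a, ])
  }, numeric(3))))
  expect_lt(max(abs(tq)), 1e-6)
})

test_that("forces match central finite differences of the total energy", {
  fx <- get_small_bundle()
  ff <- flexible_forcefield(fx$bundle, lj = test_lj_table(), lprime = 1)
  d <- make_surrogate_dimer(fx$spec, 67)
  F <- forces(d, ff)
  h <- 1e-4
  for (i in c(1, 5, 8, 12)) {   # spot-check atoms in both molecules
    for (ax in 1:3) {
      gp <- d; gp$coords[i, ax] <- gp$coords[i, ax] + h
      gm <- d; gm$coords[i, ax] <- gm$coords[i, ax] - h
      fd <- -(total_energy(gp, ff)$total -
                total_energy(gm, ff)$total) / (2 * h)
      expect_lt(abs(F[i, ax] - fd) / max(abs(fd), 1), 1e-4)
    }
  }
})

test_that("convergence criteria implement the two-part test", {
  ## constant series: converged with zero gradient and zero line RMSE
  cc <- check_convergence(rep(5, 1500), window = 1000)
  expect_true(cc$converged)
  expect_equal(cc$gradient, 0)
  expect_equal(cc$line_rmse, 0)
  ## a linear drift of 1e-3 kJ/mol/step fails the gradient criterion
  cc2 <- check_convergence(seq(0, by = -1e-3, length.out = 1500),
                           window = 1000)
  expect_false(cc2$converged)
  expect_equal(abs(cc2$gradient), 1e-3)
  expect_equal(cc2$line_rmse, 0)   # a line deviates nowhere from itself
  ## slope within tolerance and exactly on the endpoint line: converged
  cc3 <- check_convergence(seq(0, by = 5e-5, length.out = 1200),
                           window = 1000)
  expect_true(cc3$converged)
  ## an oscillation that happens to end where it started fails criterion 2
  osc <- 5 + sin(seq(0, 20 * pi, length.out = 2001))
  cc4 <- check_convergence(osc, window = 2000)
  expect_false(cc4$converged)
  expect_gt(cc4$line_rmse, 0.1)
  expect_error(check_convergence(1:10, window = 1000), "shorter")
})

test_that("the zero-Kelvin optimizer finds the two-particle LJ minimum", {
  lj <- lj_params("Ar", epsilon = 1, sigma = 3)
  g <- geometry(c("Ar", "Ar"), rbind(c(0, 0, 0), c(4.5, 0, 0)),
                molecule = c(1, 2))
  ff <- static_forcefield(lj = lj, lprime = 0, cutoff = 12)
  traj <- zero_k_optimize(g, ff, max_steps = 5000, window = 1000)
  final <- traj$geometries[[length(traj$geometries)]]
  r <- sqrt(sum((final$coords[2, ] - final$coords[1, ])^2))
  expect_lt(abs(r - 2^(1 / 6) * 3), 1e-3)
  expect_true(traj$converged)
  ## non-divergence: the running 100-step maximum never increases
  run_max <- vapply(split(traj$energies,
                          ceiling(seq_along(traj$energies) / 100)),
                    max, numeric(1))
  expect_true(all(diff(run_max) <= 1e-9))
  ## a 1-step budget returns a 1-step unconverged trajectory
  t1 <- zero_k_optimize(g, ff, max_steps = 1)
  expect_length(t1$energies, 1)
  expect_false(t1$converged)
})
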