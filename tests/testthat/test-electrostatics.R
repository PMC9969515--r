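test_that("generated solid harmonics are harmonic and match closed forms", {
  ## closed forms for l <= 2 in the Racah convention
  pts <- matrix(stats::rnorm(30), 10, 3)
  ref <- list(
    `1,-1` = pts[, 2], `1,0` = pts[, 3], `1,1` = pts[, 1],
    `2,0` = (3 * pts[, 3]^2 - rowSums(pts^2)) / 2,
    `2,1` = sqrt(3) * pts[, 1] * pts[, 3],
    `2,-1` = sqrt(3) * pts[, 2] * pts[, 3],
    `2,2` = sqrt(3) / 2 * (pts[, 1]^2 - pts[, 2]^2),
    `2,-2` = sqrt(3) * pts[, 1] * pts[, 2])
  for (key in names(ref)) {
    lm <- as.numeric(strsplit(key, ",")[[1]])
    got <- gprff:::sh_poly_eval(lm[1], lm[2], pts)
    expect_equal(got, ref[[key]], tolerance = 1e-10)
  }
  ## l = 3, 4: harmonicity (Laplacian vanishes) and homogeneity
  for (l in 3:4) {
    for (m in c(-l, 0, l - 1)) {
      p <- gprff:::sh_poly(l, m)
      rep <- cbind(p[, 1:3, drop = FALSE], 0, p[, 4])
      lap <- gprff:::rep_simplify(rbind(
        gprff:::rep_deriv(gprff:::rep_deriv(rep, 1), 1),
        gprff:::rep_deriv(gprff:::rep_deriv(rep, 2), 2),
        gprff:::rep_deriv(gprff:::rep_deriv(rep, 3), 3)))
      expect_true(nrow(lap) == 0 ||
                    max(abs(lap[, 5])) < 1e-12)  # cancellation residue
      x <- c(0.7, -1.1, 0.4)
      expect_equal(gprff:::rep_eval(rep, 2 * x),
                   2^l * gprff:::rep_eval(rep, x), tolerance = 1e-10)
    }
  }
  ## Laplace expansion fixes the normalization of every rank
  r <- c(2.0, -1.0, 1.5); s <- c(0.05, 0.02, -0.04)
  acc <- 0
  for (l in 0:4) for (m in -l:l) {
    p <- gprff:::sh_poly(l, m)
    Rs <- sum(p[, 4] * s[1]^p[, 1] * s[2]^p[, 2] * s[3]^p[, 3])
    acc <- acc + Rs *
      gprff:::rep_eval(cbind(p[, 1:3, drop = FALSE], 2 * l + 1, p[, 4]), r)
  }
  expect_equal(acc, 1 / sqrt(sum((r - s)^2)), tolerance = 1e-8)
})

test_that("moment rotation matches the Cartesian-vector oracle", {
  set.seed(19)
  mom <- matrix(stats::rnorm(25), 1, 25)
  ms <- multipole_set(mom, "local")
  ## identity leaves everything unchanged
  id <- rotate_moments(ms, diag(3))
  expect_equal(unclass(id), unclass(ms), ignore_attr = TRUE)
  for (s in 1:4) {
    R <- random_rotation(s)
    rot <- rotate_moments(ms, R)
    ## charges are scalars
    expect_equal(unname(rot[1, "Q00"]), mom[1, 1])
    ## dipoles transform exactly like Cartesian vectors
    mu_cart <- c(mom[1, 4], mom[1, 2], mom[1, 3])   # (Q11, Q1m1, Q10)
    mu_rot <- drop(R %*% mu_cart)
    expect_equal(unname(rot[1, c("Q11", "Q1m1", "Q10")]),
                 mu_rot[c(1, 2, 3)], tolerance = 1e-10)
    ## rank blocks transform orthogonally (norms preserved)
    for (l in 2:4) {
      sl <- gprff:::rank_slice(l)
      expect_equal(sum(rot[1, sl]^2), sum(mom[1, sl]^2), tolerance = 1e-10)
    }
  }
  expect_error(rotate_moments(ms, diag(c(1, 1, -1))), "proper")
})

test_that("pair interaction energies reproduce closed forms and symmetry", {
  C <- 1389.35457
  qA <- unit_moment(0, 0); qB <- unit_moment(0, 0)
  expect_equal(pair_interaction_energy(qA, qB, c(0, 0, 1), 0), C,
               tolerance = 1e-10)
  ## charge with an ideal dipole pointing along the separation axis
  muB <- unit_moment(1, 0, 0.4)
  R <- 2.5
  e <- pair_interaction_energy(qA, muB, c(0, 0, R), 1)
  expect_equal(abs(e), C * 1 * 0.4 / R^2, tolerance = 1e-10)
  ## truncation: the dipole term is invisible at lprime = 0
  expect_equal(pair_interaction_energy(qA, muB, c(0, 0, R), 0), 0)
  ## swapping the sites with R -> -R leaves the energy unchanged
  set.seed(23)
  mA <- stats::rnorm(25); mB <- stats::rnorm(25)
  rv <- c(1.2, -0.7, 2.2)
  for (lp in 0:4) {
    expect_equal(pair_interaction_energy(mA, mB, rv, lp),
                 pair_interaction_energy(mB, mA, -rv, lp),
                 tolerance = 1e-9)
  }
  expect_error(pair_interaction_energy(mA, mB, c(0, 0, 0), 2), "zero")
})

test_that("rank truncation is monotone-inclusive", {
  set.seed(29)
  mA <- stats::rnorm(25); mB <- stats::rnorm(25)
  rv <- c(2, 1, 3)
  ## with only charges present, every truncation gives the same energy
  qA <- unit_moment(0, 0, 0.3); qB <- unit_moment(0, 0, -0.8)
  e0 <- pair_interaction_energy(qA, qB, rv, 0)
  for (lp in 1:4) {
    expect_equal(pair_interaction_energy(qA, qB, rv, lp), e0,
                 tolerance = 1e-12)
  }
  ## terms present at lprime are a superset of those at lprime - 1:
  ## zeroing all components above lprime-1 makes the two agree
  for (lp in 1:4) {
    keep <- unlist(lapply(0:(lp - 1), function(l) gprff:::rank_slice(l)))
    mA2 <- numeric(25); mA2[keep] <- mA[keep]
    mB2 <- numeric(25); mB2[keep] <- mB[keep]
    expect_equal(pair_interaction_energy(mA2, mB2, rv, lp),
                 pair_interaction_energy(mA2, mB2, rv, lp - 1),
                 tolerance = 1e-9)
  }
})

test_that("intermolecular energy matches a hand-summed Coulomb double loop", {
  ## two diatomic molecules carrying charges only
  g <- geometry(c("H", "H", "H", "H"),
                rbind(c(0, 0, 0), c(0.8, 0, 0),
                      c(3.1, 0.4, 0.2), c(3.9, 0.4, 0.2)),
                molecule = c(1, 1, 2, 2))
  q <- c(0.3, -0.3, 0.5, -0.5)
  mom <- multipole_set(outer(q, unit_moment(0, 0)), "global")
  e <- intermolecular_energy(g, mom, lprime = 0, cutoff = 12)
  brute <- 0
  for (i in 1:2) for (j in 3:4) {
    brute <- brute + 1389.35457 * q[i] * q[j] /
      sqrt(sum((g$coords[j, ] - g$coords[i, ])^2))
  }
  expect_equal(e, brute, tolerance = 1e-10)
  ## a single molecule has no intermolecular energy
  mono <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_warning(e0 <- intermolecular_energy(
    mono, multipole_set(matrix(0, 2, 25), "global"), 0), "single")
  expect_equal(e0, 0)
  ## beyond the cutoff everything vanishes
  far <- g; far$coords[3:4, 1] <- far$coords[3:4, 1] + 100
  expect_equal(intermolecular_energy(far, mom, 0, cutoff = 12), 0)
})

test_that("intermolecular energy is frame-independent", {
  spec <- surrogate_spec()
  d <- make_surrogate_dimer(spec, 41)
  props <- lapply(gprff:::molecule_views(d), function(v) {
    surrogate_properties(v$geom, spec)
  })
  mom_loc <- multipole_set(
    rbind(as.matrix(props[[1]][, moment_labels()]),
          as.matrix(props[[2]][, moment_labels()])), "local")
  to_global <- function(geom) {
    rots <- unlist(lapply(gprff:::molecule_views(geom), function(v) {
      alfs <- alf_list(v$geom)
      lapply(alfs, function(a) alf_rotation(v$geom, a))
    }), recursive = FALSE)
    rotate_moments(mom_loc, rots)
  }
  e1 <- intermolecular_energy(d, to_global(d), 4, 12)
  d2 <- rigid_move(d, random_rotation(8), c(3, -2, 1))
  e2 <- intermolecular_energy(d2, to_global(d2), 4, 12)
  expect_lt(abs(e1 - e2), 1e-8)
})

test_that("molecular dipoles assemble from charges and atomic dipoles", {
  ## +/- 1 e at 1 A with no atomic dipoles: 1 e*A = 4.803 D
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  mom <- multipole_set(rbind(unit_moment(0, 0, -1), unit_moment(0, 0, 1)),
                       "global")
  d <- molecular_dipole(g, mom)
  expect_equal(d$magnitude_debye, 4.8032047, tolerance = 1e-10)
  ## neutral system: origin shift leaves the magnitude unchanged
  g2 <- g; g2$coords <- g2$coords + 5
  d2 <- molecular_dipole(g2, mom)
  expect_lt(abs(d$magnitude_debye - d2$magnitude_debye), 1e-10)
  ## all moments zero
  z <- molecular_dipole(g, multipole_set(matrix(0, 2, 25), "global"))
  expect_equal(z$magnitude_debye, 0)
})

test_that("charge errors convert to energies with the documented prefactor", {
  expect_equal(round(charge_error_energy(1, 1500, 2), 1), 1.0)
  expect_equal(charge_error_energy(1, 1500, 2), 1.0420159, tolerance = 1e-6)
  expect_equal(charge_error_energy(0, 1500, 2), 0)
  expect_equal(charge_error_energy(2, 1500, 2),
               2 * charge_error_energy(1, 1500, 2))
  expect_error(charge_error_energy(1, 1, 0), "positive")
})

test_that("the electrostatic error heatmap is an RMSE per atom pair", {
  spec <- surrogate_spec()
  d1 <- make_surrogate_dimer(spec, 51)
  d2 <- make_surrogate_dimer(spec, 52)
  exact <- lapply(list(d1, d2), function(g) {
    rots <- unlist(lapply(gprff:::molecule_views(g), function(v) {
      alfs <- alf_list(v$geom)
      lapply(alfs, function(a) alf_rotation(v$geom, a))
    }), recursive = FALSE)
    loc <- do.call(rbind, lapply(gprff:::molecule_views(g), function(v) {
      as.matrix(surrogate_properties(v$geom, spec)[, moment_labels()])
    }))
    rotate_moments(multipole_set(loc, "local"), rots)
  })
  ## perfect predictions: all-zero heatmap
  hm0 <- electrostatic_error_heatmap(list(d1, d2), exact, exact, 2)
  expect_equal(max(hm0), 0)
  expect_equal(dim(hm0), c(6, 6))
  ## a known perturbation of one charge: RMSE = |e| for a single frame
  pert <- exact
  pert[[1]][1, "Q00"] <- pert[[1]][1, "Q00"] + 0.01
  hm1 <- electrostatic_error_heatmap(list(d1), pert[1], exact[1], 0)
  rv <- d1$coords[7, ] - d1$coords[1, ]
  expected <- abs(1389.35457 * 0.01 * unname(exact[[1]][7, "Q00"]) /
                    sqrt(sum(rv^2)))
  expect_equal(hm1[1, 1], expected, tolerance = 1e-10)
  ## two frames with errors +a and -a give RMSE a: same geometry twice,
  ## the charge perturbed up in one frame and down in the other
  up <- exact[[1]]; up[1, "Q00"] <- up[1, "Q00"] + 0.01
  dn <- exact[[1]]; dn[1, "Q00"] <- dn[1, "Q00"] - 0.01
  hm_pm <- electrostatic_error_heatmap(list(d1, d1), list(up, dn),
                                       list(exact[[1]], exact[[1]]), 0)
  expect_equal(hm_pm[1, 1], expected, tolerance = 1e-10)
  ## frames with missing moments are skipped
  expect_message(
    hm2 <- electrostatic_error_heatmap(list(d1, d2), list(exact[[1]], NULL),
                                       exact, 0),
    "skipped")
  expect_equal(max(hm2), 0)
})

test_that("every low-rank tensor term matches its point-charge realization", {
  ## the independent oracle: finite point-charge arrays constructed to
  ## carry a single pure multipole component each
  dirv <- c(0.3, -0.5, 0.81); dirv <- dirv / sqrt(sum(dirv^2))
  rvec <- 10 * dirv
  for (lA in 0:2) for (lB in 0:2) {
    for (ms in list(c(min(lA, 1), -min(lB, 1)), c(-lA, lB))) {
      arrA <- point_charge_realization(lA, ms[1], extent = 0.15, seed = 2)
      arrB <- point_charge_realization(lB, ms[2], extent = 0.15, seed = 3)
      et <- pair_interaction_energy(unit_moment(lA, ms[1]),
                                    unit_moment(lB, ms[2]), rvec, 4)
      eo <- point_charge_energy(arrA, arrB, rvec)
      expect_lt(abs(et - eo) / max(abs(et), 1e-10), 1e-3)
    }
  }
})

test_that("pure tensor terms decay as R^-(lA+lB+1)", {
  dirv <- c(0.3, -0.5, 0.81); dirv <- dirv / sqrt(sum(dirv^2))
  Rs <- seq(20, 40, length.out = 6)
  for (lA in 0:2) for (lB in 0:2) {
    mA <- unit_moment(lA, min(lA, 1))
    mB <- unit_moment(lB, -min(lB, 1))
    es <- vapply(Rs, function(R) {
      abs(pair_interaction_energy(mA, mB, R * dirv, 4))
    }, numeric(1))
    slope <- stats::coef(stats::lm(log(es) ~ log(Rs)))[[2]]
    expect_lt(abs(slope + (lA + lB + 1)), 0.01)
  }
})
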