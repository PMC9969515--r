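test_that("prediction errors honour the cancellation semantics", {
  true <- rbind(c(1, 2, 3), c(0, 0, 0))
  pred <- rbind(c(1.5, 1.6, 3), c(0.2, -0.3, 0.1))
  expect_equal(prediction_errors(true, pred, "cancel"), c(0.1, 0))
  expect_equal(prediction_errors(true, pred, "sum-abs"), c(0.9, 0.6))
  expect_equal(prediction_errors(true, true, "cancel"), c(0, 0))
  expect_equal(prediction_errors(true, true, "sum-abs"), c(0, 0))
  expect_equal(prediction_errors(true, pred, "per-atom")[1, ],
               c(0.5, 0.4, 0))
  ## triangle inequality: sum-abs dominates cancel on random records
  set.seed(44)
  t2 <- matrix(stats::rnorm(60), 10, 6)
  p2 <- t2 + matrix(stats::rnorm(60, 0, 0.3), 10, 6)
  expect_true(all(prediction_errors(t2, p2, "sum-abs") >=
                    prediction_errors(t2, p2, "cancel") - 1e-12))
  expect_error(prediction_errors(t2, p2[, 1:3]), "misaligned")
})

test_that("S-curves are sorted cumulative distributions", {
  sc <- s_curve(c(0.1, 0.3, 0.2))
  expect_equal(sc$error, c(0.1, 0.2, 0.3))
  expect_equal(sc$percentile, c(100 / 3, 200 / 3, 100))
  expect_equal(s_curve_quantile(sc, 100), 0.3)
  ## flat curve for all-equal errors
  flat <- s_curve(rep(0.5, 4))
  expect_true(all(flat$error == 0.5))
  ## quantiles are monotone in the percentile
  set.seed(9)
  sc2 <- s_curve(abs(stats::rnorm(200)))
  qs <- s_curve_quantile(sc2, c(10, 25, 50, 75, 90, 100))
  expect_true(all(diff(qs) >= 0))
  ## the median of many half-normal draws sits near the closed form
  set.seed(10)
  draws <- abs(stats::rnorm(500))
  med_ref <- stats::qnorm(0.75)   # half-normal median
  expect_lt(abs(s_curve_quantile(s_curve(draws), 50) - med_ref) / med_ref,
            0.1)
  expect_error(s_curve(numeric(0)), "no errors")
  expect_error(s_curve(c(0.1, -0.2)), "nonnegative")
})

test_that("Kabsch RMSD is a proper superposition metric", {
  g <- make_formamide()
  expect_equal(kabsch_rmsd(g, g)$rmsd, 0)
  ## a rigidly moved copy superposes exactly
  g2 <- rigid_move(g, random_rotation(2), c(3, -1, 7))
  expect_lt(kabsch_rmsd(g, g2)$rmsd, 1e-10)
  ## two-point closed form: bond lengths 1.0 vs 1.2 give RMSD 0.1
  a <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  expect_equal(kabsch_rmsd(a, b)$rmsd, 0.1, tolerance = 1e-12)
  ## symmetry in its arguments
  set.seed(3)
  g3 <- g; g3$coords <- g3$coords + matrix(stats::rnorm(18, 0, 0.2), 6, 3)
  expect_lt(abs(kabsch_rmsd(g, g3)$rmsd - kabsch_rmsd(g3, g)$rmsd), 1e-10)
  ## mirror images do not superpose (proper rotations only)
  mir <- g; mir$coords[, 3] <- -mir$coords[, 3]
  g4 <- make_formamide()
  g4$coords[, 3] <- g4$coords[, 3] + c(0.3, -0.2, 0.1, 0.4, -0.3, 0.2)
  mir4 <- g4; mir4$coords[, 3] <- -mir4$coords[, 3]
  expect_gt(kabsch_rmsd(g4, mir4)$rmsd, 1e-3)
  expect_error(kabsch_rmsd(a, g), "mismatch")
})

test_that("dimer classification respects the threshold and monomer swap", {
  set.seed(13)
  refs <- lapply(1:3, function(s) make_surrogate_dimer(surrogate_spec(), s))
  names(refs) <- c("A", "B", "C")
  ## self-classification is the identity with zero RMSD
  for (lab in names(refs)) {
    cl <- classify_dimer(refs[[lab]], refs)
    expect_equal(cl$label, lab)
    expect_lt(cl$rmsd, 1e-10)
  }
  ## a rigidly moved copy still classifies
  moved <- rigid_move(refs$B, random_rotation(7), c(1, 2, 3))
  expect_equal(classify_dimer(moved, refs)$label, "B")
  ## swapped monomer blocks classify thanks to the swap correspondence
  swp <- refs$A
  perm <- c(7:12, 1:6)
  swp <- geometry(swp$elements[perm], swp$coords[perm, ],
                  molecule = swp$molecule)
  expect_equal(classify_dimer(swp, refs)$label, "A")
  ## far from every reference: unmatched, and never labelled past threshold
  stretched <- refs$A
  stretched$coords[7:12, ] <- stretched$coords[7:12, ] + 3
  cl <- classify_dimer(stretched, refs)
  expect_equal(cl$label, "unmatched")
  expect_gte(cl$rmsd, 0.2)
})

test_that("hydrogen-bond tables report textbook distances and angles", {
  ## collinear donor-H...acceptor: 180 degrees
  g <- geometry(c("N", "H", "O", "C"),
                rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(3, 2, 0)))
  t1 <- hbond_report(g, data.frame(donor = 1, h = 2, acceptor = 3,
                                   antecedent = 4))
  expect_equal(t1$h_acceptor_dist, 2)
  expect_equal(t1$donor_h_acceptor_angle, 180)
  expect_equal(t1$antecedent_angle, 90)   # right angle by construction
  ## hand-built distances on a 4-atom case
  g2 <- geometry(c("N", "H", "O", "C"),
                 rbind(c(0, 0, 0), c(0.6, 0.8, 0), c(0.6, 2.8, 0),
                       c(1.6, 2.8, 0)))
  t2 <- hbond_report(g2, data.frame(donor = 1, h = 2, acceptor = 3,
                                    antecedent = NA))
  expect_equal(t2$h_acceptor_dist, 2)
  expect_true(is.na(t2$antecedent_angle))
  expect_error(hbond_report(g2, data.frame(donor = 1, h = 9, acceptor = 3)),
               "out of range")
})

test_that("bond-change reports difference dimer halves against the monomer", {
  mono <- make_formamide()
  ## dimer of two unperturbed monomers: all deltas are zero
  dim0 <- geometry(rep(mono$elements, 2),
                   rbind(mono$coords, mono$coords + 5),
                   molecule = rep(1:2, each = 6))
  bonds <- data.frame(i = c(1, 1), j = c(2, 3), half = c(1, 2))
  r0 <- bond_change_report(mono, list(AA = dim0), bonds)
  expect_equal(r0$delta, c(0, 0))
  ## a constructed +0.012 A stretch of the C=O bond in half 1
  dim1 <- dim0
  u <- (dim1$coords[2, ] - dim1$coords[1, ])
  dim1$coords[2, ] <- dim1$coords[1, ] + u / sqrt(sum(u^2)) *
    (sqrt(sum(u^2)) + 0.012)
  r1 <- bond_change_report(mono, list(S = dim1), bonds)
  expect_equal(r1$delta[1], 0.012)
  ## shortening reports a negative delta
  dim2 <- dim0
  v <- (dim2$coords[9, ] - dim2$coords[7, ])
  dim2$coords[9, ] <- dim2$coords[7, ] + v / sqrt(sum(v^2)) *
    (sqrt(sum(v^2)) - 0.02)
  r2 <- bond_change_report(mono, list(S = dim2), bonds)
  expect_equal(r2$delta[2], -0.02)
  expect_error(bond_change_report(mono, list(X = dim0),
                                  data.frame(i = 1, j = 9)),
               "out of range")
})

test_that("energy rankings are ascending, relative and order-independent", {
  e <- c(A = -10, B = -8)
  r <- energy_ranking(e)
  expect_equal(r$label, c("A", "B"))
  expect_equal(r$relative, c(0, 2))
  ## shuffled input gives the same ranking
  r2 <- energy_ranking(e[c("B", "A")])
  expect_equal(r2, r)
  ## equal energies: stable label-order tie-break
  r3 <- energy_ranking(c(Z = 1, M = 1, A = 0))
  expect_equal(r3$label, c("A", "M", "Z"))
  expect_error(energy_ranking(c(A = 1)), "at least 2")
  expect_error(energy_ranking(stats::setNames(c(1, 2), c("A", "A"))),
               "unique")
})
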