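#' Analytic molecular-property surrogate
#'
#' A fully analytic stand-in for the quantum-chemistry stage of the
#' pipeline: a formamide-like 6-atom molecule with a Morse-bond / harmonic
#' angle / cosine-torsion molecular energy whose minimum and equilibrium
#' geometry are known in closed form, partitioned into per-atom energies
#' that sum exactly to the molecular energy; geometry-dependent charges
#' from electronegativity equalization (summing exactly to zero);
#' bond-vector atomic dipoles; and smooth local-frame functions of the ALF
#' features for quadrupole and higher moments. Everything is C1 in the
#' coordinates, so GP models can learn it, and all reference values
#' (equilibrium bond lengths, molecular dipole) are computable exactly.
#'
#' The surrogate's functional forms are chosen for smoothness and known
#' minima, not physical fidelity.
#'
#' @name synthetic_oracle
NULL

#' Default formamide-like surrogate specification
#'
#' Six atoms (C, O, N, H on C, two H on N; 3N-6 = 12 features), planar
#' equilibrium, Morse bonds, harmonic angles, twofold cosine torsions.
#'
#' @param noise standard deviation of optional Gaussian noise added to the
#'   atomic energies (kJ/mol; default 0 = noiseless).
#' @param moment_seed seed fixing the higher-moment coefficient scheme.
#' @return a list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(noise = 0, moment_seed = 7L) {
  deg <- pi / 180
  spec <- list(
    elements = c("C", "O", "N", "H", "H", "H"),
    ## bonds: i, j, D_e (kJ/mol), a (1/A), r_e (A)
    bonds = data.frame(
      i = c(1, 1, 1, 3, 3), j = c(2, 3, 4, 5, 6),
      D = c(750, 450, 430, 450, 450),
      a = c(2.2, 2.0, 1.8, 2.2, 2.2),
      re = c(1.22, 1.36, 1.10, 1.01, 1.01)),
    ## angles: i, j (apex), k, force constant (kJ/mol/rad^2), theta0 (rad)
    angles = data.frame(
      i = c(2, 2, 3, 1, 1, 5), j = c(1, 1, 1, 3, 3, 3),
      k = c(3, 4, 4, 5, 6, 6),
      kf = c(300, 300, 300, 250, 250, 250),
      theta0 = c(125, 122, 113, 119, 121, 120) * deg),
    ## torsions: a-b-c-d, force constant, phi0 (rad); E = kf/2 (1-cos 2(phi-phi0))
    torsions = data.frame(
      a = c(2, 2, 4, 4), b = c(1, 1, 1, 1), c = c(3, 3, 3, 3),
      d = c(5, 6, 5, 6),
      kf = c(40, 40, 40, 40),
      phi0 = c(0, pi, pi, 0)),
    ## electronegativity equalization (eV-scale parameters; charges in e)
    eem = list(chi = c(5.7, 8.5, 7.5, 4.5, 4.5, 4.5),
               eta = c(10, 13, 12, 12, 12, 12),
               jscale = 14.4, jsoft = 0.9),
    ## bond-dipole coefficients (e*A), by bond row, applied to each end
    bond_dipole = c(0.20, 0.15, 0.05, 0.10, 0.10),
    noise = noise)
  class(spec) <- "surrogate_spec"
  spec$equilibrium <- surrogate_equilibrium(spec)
  ## higher-moment coefficient scheme: fixed small smooth functions of the
  ## first two features about their equilibrium values
  set.seed(moment_seed)
  nm <- moment_labels()
  amp <- rep(c(0, 0, 0, 0, 0.35, 0.35, 0.35, 0.35, 0.35,
               rep(0.15, 7), rep(0.06, 9)))
  spec$moment_c0 <- matrix(stats::runif(6 * 25, -1, 1), 6, 25,
                           dimnames = list(NULL, nm)) * rep(amp, each = 6)
  spec$moment_c1 <- matrix(stats::runif(6 * 25, -1, 1), 6, 25) *
    rep(amp, each = 6) * 0.5
  spec$moment_c2 <- matrix(stats::runif(6 * 25, -1, 1), 6, 25) *
    rep(amp, each = 6) * 0.5
  eqf <- compute_features(spec$equilibrium)
  spec$eq_features <- lapply(eqf, `[[`, "values")
  spec
}

## place atom D given C(bond), B(angle), A(torsion): NERF construction
place_atom <- function(A, B, C, r, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- pracma::cross(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d <- r * (-cos(theta) * bc + sin(theta) * (cos(phi) * m + sin(phi) * n))
  C + d
}

#' Equilibrium geometry of a surrogate molecule
#' @param spec a `surrogate_spec` (the topology/parameter fields are used).
#' @return a [geometry()] at the exact energy minimum (all bonds at r_e,
#'   angles at theta0, torsions at phi0).
#' @export
surrogate_equilibrium <- function(spec) {
  deg <- pi / 180
  b <- spec$bonds
  re <- function(i, j) b$re[(b$i == i & b$j == j) | (b$i == j & b$j == i)]
  th <- function(i, j, k) {
    a <- spec$angles
    a$theta0[(a$i == i & a$j == j & a$k == k) |
               (a$i == k & a$j == j & a$k == i)]
  }
  C <- c(0, 0, 0)
  O <- c(re(1, 2), 0, 0)
  ang <- th(2, 1, 3)
  N <- re(1, 3) * c(cos(ang), sin(ang), 0)
  angH <- th(2, 1, 4)
  H4 <- re(1, 4) * c(cos(-angH), sin(-angH), 0)
  H5 <- place_atom(O, C, N, re(3, 5), th(1, 3, 5), 0)   # cis to O
  H6 <- place_atom(O, C, N, re(3, 6), th(1, 3, 6), pi)  # trans to O
  geometry(spec$elements, rbind(C, O, N, H4, H5, H6),
           comment = "surrogate equilibrium")
}

vec_angle <- function(u, v) {
  atan2(sqrt(sum(pracma::cross(u, v)^2)), sum(u * v))
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  m <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m * n2), sum(n1 * n2))
}

#' Molecular surrogate energy and its exact per-atom partition
#'
#' Each bond/angle/torsion term is split equally among its participating
#' atoms, so the atomic energies sum to the molecular energy exactly.
#'
#' @param geom a [geometry()] matching the spec's topology.
#' @param spec a `surrogate_spec`.
#' @return list with `molecular` (kJ/mol) and `atomic` (length-N vector).
#' @export
surrogate_energy <- function(geom, spec) {
  n <- n_atoms(geom)
  if (n != length(spec$elements) ||
      !all(geom$elements == spec$elements)) {
    stop("geometry does not match the surrogate topology")
  }
  x <- geom$coords
  atomic <- numeric(n)
  for (q in seq_len(nrow(spec$bonds))) {
    b <- spec$bonds[q, ]
    r <- sqrt(sum((x[b$j, ] - x[b$i, ])^2))
    e <- b$D * (1 - exp(-b$a * (r - b$re)))^2
    atomic[c(b$i, b$j)] <- atomic[c(b$i, b$j)] + e / 2
  }
  for (q in seq_len(nrow(spec$angles))) {
    a <- spec$angles[q, ]
    th <- vec_angle(x[a$i, ] - x[a$j, ], x[a$k, ] - x[a$j, ])
    e <- a$kf / 2 * (th - a$theta0)^2
    atomic[c(a$i, a$j, a$k)] <- atomic[c(a$i, a$j, a$k)] + e / 3
  }
  for (q in seq_len(nrow(spec$torsions))) {
    t <- spec$torsions[q, ]
    phi <- dihedral(x[t$a, ], x[t$b, ], x[t$c, ], x[t$d, ])
    e <- t$kf / 2 * (1 - cos(2 * (phi - t$phi0)))
    idx <- c(t$a, t$b, t$c, t$d)
    atomic[idx] <- atomic[idx] + e / 4
  }
  list(molecular = sum(atomic), atomic = atomic)
}

## geometry-dependent charges: electronegativity equalization, sum(q) = 0
surrogate_charges <- function(geom, spec) {
  n <- n_atoms(geom)
  p <- spec$eem
  d <- as.matrix(stats::dist(geom$coords))
  J <- p$jscale / sqrt(d^2 + p$jsoft^2)
  diag(J) <- 2 * p$eta
  A <- rbind(cbind(J, 1), c(rep(1, n), 0))
  sol <- solve(A, c(-p$chi, 0))
  q <- sol[seq_len(n)]
  q - mean(q)  # exact neutrality against roundoff
}

#' Per-atom surrogate properties for one geometry
#'
#' Atomic energies (partitioned exactly), charges (electronegativity
#' equalization), atomic dipoles (bond-dipole vectors rotated into each
#' atom's ALF) and smooth local-frame feature functions for ranks 2-4.
#'
#' @param geom a [geometry()] matching the spec topology.
#' @param spec a `surrogate_spec`.
#' @param alfs optional precomputed ALF list.
#' @return data.frame with columns `atom`, `energy`, and the 25 moment
#'   columns (local frame); the molecular energy is attached as attribute
#'   `molecular_energy`.
#' @export
surrogate_properties <- function(geom, spec, alfs = alf_list(geom)) {
  n <- n_atoms(geom)
  en <- surrogate_energy(geom, spec)
  q <- surrogate_charges(geom, spec)
  feats <- compute_features(geom, alfs)
  mom <- matrix(0, n, 25, dimnames = list(NULL, moment_labels()))
  mom[, "Q00"] <- q
  ## atomic dipoles: sum of bond-dipole contributions, then local frame
  for (a in seq_len(n)) {
    mu <- c(0, 0, 0)
    for (qq in seq_len(nrow(spec$bonds))) {
      b <- spec$bonds[qq, ]
      if (b$i == a || b$j == a) {
        other <- if (b$i == a) b$j else b$i
        u <- geom$coords[other, ] - geom$coords[a, ]
        mu <- mu + spec$bond_dipole[qq] * u / sqrt(sum(u^2))
      }
    }
    mu_loc <- drop(crossprod(alf_rotation(geom, alfs[[a]]), mu))
    mom[a, c("Q11", "Q1m1", "Q10")] <- mu_loc  # (x, y, z)
    ## ranks 2-4: smooth local functions of the first two features
    f <- feats[[a]]$values
    df1 <- f[1] - spec$eq_features[[a]][1]
    df2 <- f[2] - spec$eq_features[[a]][2]
    hi <- 5:25  # quadrupole block starts at component 5
    mom[a, hi] <- spec$moment_c0[a, hi] + spec$moment_c1[a, hi] * df1 +
      spec$moment_c2[a, hi] * df2
  }
  energy <- en$atomic
  if (spec$noise > 0) energy <- energy + stats::rnorm(n, 0, spec$noise)
  out <- data.frame(atom = seq_len(n), energy = energy)
  out <- cbind(out, as.data.frame(mom))
  attr(out, "molecular_energy") <- en$molecular
  out
}

#' Exact molecular dipole of the surrogate at a geometry
#' @param geom a [geometry()].
#' @param spec a `surrogate_spec`.
#' @return list as from [molecular_dipole()].
#' @export
surrogate_molecular_dipole <- function(geom, spec) {
  alfs <- alf_list(geom)
  props <- surrogate_properties(geom, spec, alfs)
  loc <- multipole_set(as.matrix(props[, moment_labels()]), "local")
  rots <- lapply(alfs, function(a) alf_rotation(geom, a))
  molecular_dipole(geom, rotate_moments(loc, rots))
}

#' Sample a pool of thermally distorted geometries
#'
#' Seeded Gaussian Cartesian distortions about the surrogate equilibrium
#' (spread scaling with `temperature_scale`, emulating a 300 K classical
#' trajectory), composed with a random rigid rotation and translation per
#' frame so that frame-invariance of the featurization is exercised.
#'
#' @param spec a `surrogate_spec`.
#' @param n_frames number of geometries (>= 1).
#' @param temperature_scale distortion scale (1 = default spread, 0.04 A
#'   per Cartesian coordinate; 0 = exact equilibrium copies).
#' @param seed RNG seed.
#' @return list of geometries.
#' @export
sample_pool <- function(spec, n_frames, temperature_scale = 1, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  eq <- spec$equilibrium
  n <- n_atoms(eq)
  lapply(seq_len(n_frames), function(f) {
    disp <- matrix(stats::rnorm(3 * n, 0, 0.04 * temperature_scale), n, 3)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    shift <- stats::runif(3, -1, 1)
    geometry(eq$elements, t(R %*% t(eq$coords + disp)) + rep(shift, each = n),
             comment = sprintf("surrogate frame %d", f))
  })
}

#' Build a pool property table in the tabular exchange format
#' @param geoms list of geometries from [sample_pool()].
#' @param spec a `surrogate_spec`.
#' @return data.frame keyed by `(frame, atom)` as consumed by
#'   [run_training()]; per-frame molecular energies attached as attribute
#'   `molecular_energy`.
#' @export
surrogate_property_table <- function(geoms, spec) {
  rows <- lapply(seq_along(geoms), function(f) {
    p <- surrogate_properties(geoms[[f]], spec)
    cbind(frame = f, p)
  })
  out <- do.call(rbind, rows)
  attr(out, "molecular_energy") <-
    vapply(rows, function(r) sum(r$energy), numeric(1))
  out
}

#' End-to-end parameter-recovery harness
#'
#' Trains GP models on a surrogate pool, then checks that (i) the
#' validation S-curve can be formed, (ii) zero-Kelvin optimization from a
#' distorted start recovers the surrogate equilibrium bond lengths, and
#' (iii) the predicted molecular dipole at equilibrium matches the
#' surrogate's.
#'
#' @param spec a `surrogate_spec`.
#' @param config passed to [run_training()] (plus `n_pool`, default 1500;
#'   `start_temperature`, default 0.5; `max_steps`, default 3000;
#'   `window`, default 500).
#' @return list with `bundle`, `s_curve`, `bond_lengths` (recovered vs
#'   reference), `max_bond_error`, `dipole` (predicted vs reference
#'   magnitude in Debye), `dipole_rel_error`, `trajectory`.
#' @export
end_to_end_recovery_test <- function(spec = surrogate_spec(),
                                     config = list()) {
  cfg <- utils::modifyList(
    list(n_pool = 1500, n_valid = 500, n_final = 400, batch = 91,
         refit_every = 100, n_starts = 4, seed = 1,
         start_temperature = 0.5, max_steps = 3000, window = 500,
         moment_columns = c("Q00", "Q1m1", "Q10", "Q11")),
    config)
  pool <- sample_pool(spec, cfg$n_pool, 1, cfg$seed)
  props <- surrogate_property_table(pool, spec)
  if (max(vapply(seq_len(n_atoms(pool[[1]])), function(a) {
    stats::sd(props$energy[props$atom == a])
  }, numeric(1))) < 1e-12) {
    stop("recovery stage 'training': degenerate pool (no spread in targets)")
  }
  bundle <- run_training(pool, props, cfg)
  ## (i) validation S-curve of molecular-energy errors
  sc <- s_curve(validation_errors(bundle, pool, props, mode = "cancel"))
  ## (ii) zero-K optimization from a distorted start
  ff <- flexible_forcefield(bundle, lj = NULL, lprime = 0, cutoff = 12)
  start <- sample_pool(spec, 1, cfg$start_temperature, cfg$seed + 17)[[1]]
  traj <- zero_k_optimize(start, ff, max_steps = cfg$max_steps,
                          window = cfg$window)
  final <- traj$geometries[[length(traj$geometries)]]
  bl <- vapply(seq_len(nrow(spec$bonds)), function(q) {
    sqrt(sum((final$coords[spec$bonds$j[q], ] -
                final$coords[spec$bonds$i[q], ])^2))
  }, numeric(1))
  bond_tab <- data.frame(bond = paste0(spec$elements[spec$bonds$i],
                                       spec$bonds$i, "-",
                                       spec$elements[spec$bonds$j],
                                       spec$bonds$j),
                         reference = spec$bonds$re, recovered = bl,
                         error = bl - spec$bonds$re)
  ## (iii) predicted vs exact molecular dipole at equilibrium
  eq <- spec$equilibrium
  pred_mom <- predict_moments(bundle, eq)
  dip_pred <- molecular_dipole(eq, pred_mom)
  dip_ref <- surrogate_molecular_dipole(eq, spec)
  rel <- abs(dip_pred$magnitude_debye - dip_ref$magnitude_debye) /
    dip_ref$magnitude_debye
  list(bundle = bundle, s_curve = sc, bond_lengths = bond_tab,
       max_bond_error = max(abs(bond_tab$error)),
       dipole = c(predicted = dip_pred$magnitude_debye,
                  reference = dip_ref$magnitude_debye),
       dipole_rel_error = rel, trajectory = traj)
}

## molecular-energy validation errors of a trained bundle
validation_errors <- function(bundle, geoms, props, mode = "cancel") {
  n_at <- length(bundle$energy_models)
  idx <- bundle$split$valid
  pred <- vapply(seq_len(n_at), function(a) {
    gpr_predict(bundle$energy_models[[a]],
                bundle$features_by_atom[[a]][idx, , drop = FALSE])
  }, numeric(length(idx)))
  true <- vapply(seq_len(n_at), function(a) {
    rec <- props[props$atom == a, ]
    rec[order(rec$frame), ]$energy[idx]
  }, numeric(length(idx)))
  prediction_errors(true, pred, mode = mode)
}

## predict a full local multipole set with a bundle's moment models and
## rotate to the global frame
predict_moments <- function(bundle, geom) {
  n_at <- n_atoms(geom)
  alfs <- alf_list(geom)
  feats <- compute_features(geom, alfs)
  mom <- matrix(0, n_at, 25, dimnames = list(NULL, moment_labels()))
  for (col in names(bundle$moment_models)) {
    mom[, col] <- vapply(seq_len(n_at), function(a) {
      gpr_predict(bundle$moment_models[[col]][[a]], feats[[a]]$values)
    }, numeric(1))
  }
  rots <- lapply(alfs, function(a) alf_rotation(geom, a))
  rotate_moments(multipole_set(mom, "local"), rots)
}
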