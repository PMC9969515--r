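#' Force-field evaluation and zero-Kelvin optimization
#'
#' Two force-field modes share one evaluator. In `flexible` mode the
#' intramolecular energy of each molecule is the sum of its GP-predicted
#' atomic energies and the multipole moments are re-predicted at every
#' geometry; in `static` mode the monomer energy and local-frame moments
#' are frozen at reference values (the moments still ride on each atom's
#' local frame, so they rotate with the molecule). Molecules interact
#' through spherical-tensor multipole electrostatics (square truncation at
#' rank L') plus Lennard-Jones dispersion/repulsion, both with a real-space
#' cutoff in a large non-periodic box.
#'
#' @name simulation
NULL

#' Build a flexible (machine-learned) force field
#'
#' @param bundle trained model bundle from [run_training()] (per-atom
#'   energy models, optional moment models).
#' @param lj an [lj_params()] table or `NULL` (no LJ term).
#' @param lprime multipole truncation rank, 0..4.
#' @param cutoff electrostatics/LJ cutoff, Angstrom.
#' @return object of class `forcefield`.
#' @export
flexible_forcefield <- function(bundle, lj = NULL, lprime = 3, cutoff = 12) {
  structure(list(mode = "flexible", energy_models = bundle$energy_models,
                 moment_models = bundle$moment_models, lj = lj,
                 lprime = lprime, cutoff = cutoff),
            class = "forcefield")
}

#' Build a static-moments (rigid multipoles + LJ) force field
#'
#' @param static_moments local-frame [multipole_set()] of the reference
#'   monomer (one row per monomer atom).
#' @param monomer_energy frozen intramolecular energy per molecule, kJ/mol.
#' @param lj an [lj_params()] table or `NULL`.
#' @param lprime truncation rank, 0..4.
#' @param cutoff cutoff in Angstrom.
#' @return object of class `forcefield`.
#' @export
static_forcefield <- function(static_moments = NULL, monomer_energy = 0,
                              lj = NULL, lprime = 3, cutoff = 12) {
  if (!is.null(static_moments) &&
      moment_frame(static_moments) != "local") {
    stop("static moments must be local-frame")
  }
  structure(list(mode = "static", static_moments = static_moments,
                 monomer_energy = monomer_energy, lj = lj,
                 lprime = lprime, cutoff = cutoff),
            class = "forcefield")
}

## molecule views: sub-geometries plus index maps
molecule_views <- function(geom) {
  lapply(unique(geom$molecule), function(m) {
    idx <- which(geom$molecule == m)
    list(idx = idx,
         geom = geometry(geom$elements[idx], geom$coords[idx, , drop = FALSE],
                         comment = geom$comment))
  })
}

#' Lennard-Jones energy over intermolecular pairs
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]` with Lorentz-Berthelot combining
#' (arithmetic sigma, geometric epsilon); atom types are element symbols.
#'
#' @param geom a [geometry()] with molecule labels.
#' @param params an [lj_params()] table covering every element present.
#' @param cutoff pair cutoff, Angstrom.
#' @return energy in kJ/mol.
#' @export
lj_energy <- function(geom, params, cutoff = 12) {
  n <- n_atoms(geom)
  ti <- match(geom$elements, params$type)
  if (anyNA(ti)) {
    stop("no LJ parameters for type(s): ",
         paste(unique(geom$elements[is.na(ti)]), collapse = ", "))
  }
  e <- 0
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (geom$molecule[i] == geom$molecule[j]) next
      r <- sqrt(sum((geom$coords[j, ] - geom$coords[i, ])^2))
      if (r > cutoff) next
      eps <- sqrt(params$epsilon[ti[i]] * params$epsilon[ti[j]])
      sig <- (params$sigma[ti[i]] + params$sigma[ti[j]]) / 2
      sr6 <- (sig / r)^6
      e <- e + 4 * eps * (sr6^2 - sr6)
    }
  }
  e
}

## analytic LJ forces (N x 3)
lj_forces <- function(geom, params, cutoff = 12) {
  n <- n_atoms(geom)
  ti <- match(geom$elements, params$type)
  F <- matrix(0, n, 3)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (geom$molecule[i] == geom$molecule[j]) next
      rv <- geom$coords[j, ] - geom$coords[i, ]
      r <- sqrt(sum(rv^2))
      if (r > cutoff) next
      eps <- sqrt(params$epsilon[ti[i]] * params$epsilon[ti[j]])
      sig <- (params$sigma[ti[i]] + params$sigma[ti[j]]) / 2
      sr6 <- (sig / r)^6
      ## dE/dr = 4 eps (-12 sr12 + 6 sr6)/r; force on j = -dE/dr * rv/r
      dEdr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
      fj <- -dEdr * rv / r
      F[j, ] <- F[j, ] + fj
      F[i, ] <- F[i, ] - fj
    }
  }
  F
}

has_moments <- function(ff) {
  if (ff$mode == "static") !is.null(ff$static_moments)
  else length(ff$moment_models) > 0
}

## per-molecule local moments under a force field, rotated to global
predicted_global_moments <- function(geom, ff, views) {
  mom <- matrix(0, n_atoms(geom), 25,
                dimnames = list(NULL, moment_labels()))
  rots <- vector("list", n_atoms(geom))
  for (v in views) {
    if (length(v$idx) < 3L) {
      ## too small for a local frame: only isotropic (charge) moments can
      ## be carried, with the identity rotation
      if (ff$mode == "static") mom[v$idx, ] <- unclass(ff$static_moments)
      for (a in v$idx) rots[[a]] <- diag(3)
      next
    }
    alfs <- alf_list(v$geom)
    if (ff$mode == "flexible") {
      feats <- compute_features(v$geom, alfs)
      for (col in names(ff$moment_models)) {
        mom[v$idx, col] <- vapply(seq_along(v$idx), function(a) {
          gpr_predict(ff$moment_models[[col]][[a]], feats[[a]]$values)
        }, numeric(1))
      }
    } else {
      mom[v$idx, ] <- unclass(ff$static_moments)
    }
    for (a in seq_along(v$idx)) {
      rots[[v$idx[a]]] <- alf_rotation(v$geom, alfs[[a]])
    }
  }
  rotate_moments(multipole_set(mom, "local"), rots)
}

intermolecular_elec <- function(geom, ff, views) {
  gm <- predicted_global_moments(geom, ff, views)
  suppressWarnings(intermolecular_energy(geom, gm, ff$lprime, ff$cutoff))
}

#' Total force-field energy with per-term decomposition
#'
#' @param geom a [geometry()] whose molecules each match the monomer
#'   topology the force field was built for.
#' @param ff a `forcefield`.
#' @return list with `total`, `intra` (sum of per-molecule intramolecular
#'   energies), `electrostatic`, `lj` and `intra_by_molecule` (kJ/mol).
#' @export
total_energy <- function(geom, ff) {
  views <- molecule_views(geom)
  intra <- vapply(views, function(v) {
    if (ff$mode == "flexible") {
      feats <- compute_features(v$geom)
      sum(vapply(seq_along(v$idx), function(a) {
        gpr_predict(ff$energy_models[[a]], feats[[a]]$values)
      }, numeric(1)))
    } else {
      ff$monomer_energy
    }
  }, numeric(1))
  multi <- length(views) > 1L
  elec <- if (multi && has_moments(ff)) {
    intermolecular_elec(geom, ff, views)
  } else 0
  elj <- if (multi && !is.null(ff$lj)) {
    lj_energy(geom, ff$lj, ff$cutoff)
  } else 0
  list(total = sum(intra) + elec + elj, intra = sum(intra),
       electrostatic = elec, lj = elj, intra_by_molecule = intra)
}

#' Per-atom forces under a force field
#'
#' Intramolecular forces are analytic: the chain rule through the GP
#' kernel gradient and the exact ALF feature Jacobian (the features of
#' every atom A exert a force on every atom B they depend on).
#' Lennard-Jones forces are analytic. The intermolecular multipole term
#' uses central finite differences (step 1e-5 A) of the electrostatic
#' energy, including the geometry dependence of the predicted moments.
#'
#' @param geom a [geometry()].
#' @param ff a `forcefield`.
#' @return N x 3 matrix of forces, kJ/mol/A.
#' @export
forces <- function(geom, ff) {
  n <- n_atoms(geom)
  F <- matrix(0, n, 3)
  views <- molecule_views(geom)
  if (ff$mode == "flexible") {
    for (v in views) {
      nm <- length(v$idx)
      alfs <- alf_list(v$geom)
      feats <- compute_features(v$geom, alfs)
      J <- feature_jacobian(v$geom, alfs)
      grad <- numeric(3 * nm)
      for (a in seq_len(nm)) {
        g <- gpr_gradient(ff$energy_models[[a]], feats[[a]]$values)
        grad <- grad + drop(crossprod(J[[a]], g))
      }
      F[v$idx, ] <- F[v$idx, ] - matrix(grad, nm, 3, byrow = TRUE)
    }
  }
  multi <- length(views) > 1L
  if (multi && has_moments(ff)) {
    h <- 1e-5
    for (i in seq_len(n)) {
      for (ax in 1:3) {
        gp <- geom; gp$coords[i, ax] <- gp$coords[i, ax] + h
        gm <- geom; gm$coords[i, ax] <- gm$coords[i, ax] - h
        F[i, ax] <- F[i, ax] -
          (intermolecular_elec(gp, ff, molecule_views(gp)) -
             intermolecular_elec(gm, ff, molecule_views(gm))) / (2 * h)
      }
    }
  }
  if (multi && !is.null(ff$lj)) {
    F <- F + lj_forces(geom, ff$lj, ff$cutoff)
  }
  F
}

#' Convergence test for an optimization energy series
#'
#' Two criteria over a trailing window of `window` steps: (1) the absolute
#' gradient between the final step and the step `window` earlier is at
#' most `grad_tol` (kJ/mol per step); (2) the RMSE of the window's
#' energies about the straight line joining its endpoints — the sum of
#' squared deviations divided by `window`, square-rooted — is below
#' `rmse_tol` (kJ/mol). Both must hold.
#'
#' @param energy_series numeric energy per step, kJ/mol.
#' @param window trailing window length (default 1000 steps).
#' @param grad_tol gradient threshold, kJ/mol/step (default 1e-4).
#' @param rmse_tol line-deviation threshold, kJ/mol (default 0.1).
#' @return list with `converged`, `gradient`, `line_rmse`.
#' @export
check_convergence <- function(energy_series, window = 1000,
                              grad_tol = 1e-4, rmse_tol = 0.1) {
  N <- length(energy_series)
  if (N <= window) stop("energy series shorter than the window")
  e0 <- energy_series[N - window]
  e1 <- energy_series[N]
  gradient <- (e1 - e0) / window
  line <- e0 + (e1 - e0) * (0:window) / window
  dev <- energy_series[(N - window):N] - line
  line_rmse <- sqrt(sum(dev^2) / window)
  list(converged = abs(gradient) <= grad_tol && line_rmse < rmse_tol,
       gradient = gradient, line_rmse = line_rmse)
}

## 10 K Maxwell-Boltzmann mean speed in A/fs for masses in g/mol
cap_speed <- function(mass, temperature = 10) {
  .SPEED_UNIT * sqrt(8 * .KB_KJMOL * temperature / (pi * mass))
}

#' Zero-Kelvin (quasi-static) geometry optimizer
#'
#' Velocity-Verlet dynamics in which, after every step, each atom's
#' velocity is zeroed if it opposes the current force on the atom and is
#' rescaled so its speed never exceeds the 10 K Maxwell-Boltzmann mean
#' speed for its mass: molecules drift down the force field without
#' thermal kinetic energy. The run stops when [check_convergence()]
#' passes or `max_steps` is reached; the optimized structure is the final
#' step.
#'
#' @param geom starting [geometry()].
#' @param ff a `forcefield`.
#' @param max_steps step budget (default 3000).
#' @param dt timestep in femtoseconds (default 1).
#' @param window,grad_tol,rmse_tol convergence settings, see
#'   [check_convergence()].
#' @param keep_every store every k-th geometry (the final geometry is
#'   always stored; default 10).
#' @return object of class `optimization_trajectory`: `energies`,
#'   `max_force`, `geometries`, `converged`, `converged_step`, `dt`.
#' @export
zero_k_optimize <- function(geom, ff, max_steps = 3000, dt = 1,
                            window = 1000, grad_tol = 1e-4, rmse_tol = 0.1,
                            keep_every = 10) {
  n <- n_atoms(geom)
  mass <- element_mass(geom$elements)
  vcap <- cap_speed(mass)
  vel <- matrix(0, n, 3)
  cur <- geom
  Fc <- forces(cur, ff)
  energies <- numeric(0)
  maxf <- numeric(0)
  geoms <- list()
  converged <- FALSE
  converged_step <- NA_integer_
  step <- 0L
  err <- NULL
  while (step < max_steps) {
    step <- step + 1L
    res <- tryCatch({
      acc <- .ACC_UNIT * Fc / mass
      vel <- vel + 0.5 * dt * acc
      cur$coords <- cur$coords + dt * vel
      Fn <- forces(cur, ff)
      vel <- vel + 0.5 * dt * (.ACC_UNIT * Fn / mass)
      ## zero-Kelvin rule: follow the force, never faster than at 10 K
      for (a in seq_len(n)) {
        if (sum(vel[a, ] * Fn[a, ]) < 0) {
          vel[a, ] <- 0
        } else {
          sp <- sqrt(sum(vel[a, ]^2))
          if (sp > vcap[a]) vel[a, ] <- vel[a, ] * vcap[a] / sp
        }
      }
      Fn
    }, error = function(e) e)
    if (!inherits(res, "error")) Fc <- res
    if (inherits(res, "error")) { err <- res; break }
    e_tot <- total_energy(cur, ff)$total
    energies <- c(energies, e_tot)
    maxf <- c(maxf, max(abs(Fc)))
    if (step %% keep_every == 0L) geoms[[length(geoms) + 1L]] <- cur
    if (step > window) {
      cc <- check_convergence(energies, window, grad_tol, rmse_tol)
      if (cc$converged) {
        converged <- TRUE
        converged_step <- step
        break
      }
    }
  }
  if (length(geoms) == 0L || !identical(geoms[[length(geoms)]], cur)) {
    geoms[[length(geoms) + 1L]] <- cur
  }
  out <- structure(
    list(energies = energies, max_force = maxf, geometries = geoms,
         converged = converged, converged_step = converged_step, dt = dt),
    class = "optimization_trajectory")
  if (!is.null(err)) {
    cond <- simpleError(paste0("force evaluation failed at step ", step,
                               ": ", conditionMessage(err)))
    cond$trajectory <- out  # partial trajectory up to the failure
    stop(cond)
  }
  out
}

#' @export
print.optimization_trajectory <- function(x, ...) {
  cat(sprintf(
    "optimization_trajectory: %d steps (dt %g fs), %s, final E %.4f kJ/mol\n",
    length(x$energies), x$dt,
    if (x$converged) sprintf("converged at step %d", x$converged_step)
    else "not converged", x$energies[length(x$energies)]))
  invisible(x)
}

#' Write an optimization trajectory (XYZ frames + energy CSV)
#' @param traj an `optimization_trajectory`.
#' @param xyz_path multi-frame XYZ output path.
#' @param csv_path per-step energy CSV output path.
#' @return invisibly, a list of the two paths.
#' @export
write_trajectory <- function(traj, xyz_path, csv_path) {
  write_xyz(traj$geometries, xyz_path)
  utils::write.csv(
    data.frame(step = seq_along(traj$energies), energy = traj$energies,
               max_force = traj$max_force),
    csv_path, row.names = FALSE)
  invisible(list(xyz = xyz_path, csv = csv_path))
}
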