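#' Multipole sets
#'
#' A multipole set stores, per atom, the 25 real spherical-tensor moment
#' components Q_lm for l = 0..4 (units e * A^l), as an N x 25 matrix with
#' columns `Q00, Q1m1, Q10, Q11, ..., Q44` and a frame tag: `"local"` (each
#' atom's own ALF) or `"global"` (the lab frame). Dipole components map to
#' Cartesian vectors as (Q11, Q1m1, Q10) = (mu_x, mu_y, mu_z).
#'
#' @param mat numeric N x 25 matrix (or something coercible).
#' @param frame `"local"` or `"global"`.
#' @return a `multipole_set` object.
#' @export
multipole_set <- function(mat, frame = c("local", "global")) {
  frame <- match.arg(frame)
  mat <- as.matrix(mat)
  if (ncol(mat) != 25L) stop("a multipole set has 25 components per atom")
  if (!all(is.finite(mat))) stop("non-finite moment components")
  colnames(mat) <- moment_labels()
  structure(mat, frame = frame, class = c("multipole_set", "matrix", "array"))
}

moment_frame <- function(m) attr(m, "frame")

## slice indices of rank l within the 25-component ordering
rank_slice <- function(l) {
  offset <- if (l == 0) 0L else sum(2 * (0:(l - 1)) + 1)
  offset + seq_len(2 * l + 1)
}

#' Rotate local-frame moments to the global frame
#'
#' Charges are unchanged; rank-l components transform under the rank-l real
#' Wigner matrix of each atom's rotation. Typically the rotation is each
#' atom's [alf_rotation()], so that moments predicted in the ALF can be
#' combined across molecules.
#'
#' @param moments a local-frame [multipole_set()].
#' @param rotations a single 3 x 3 proper rotation matrix, or a list with
#'   one per atom.
#' @return a global-frame `multipole_set`.
#' @export
rotate_moments <- function(moments, rotations) {
  if (is.matrix(rotations)) {
    rotations <- rep(list(rotations), nrow(moments))
  }
  if (length(rotations) != nrow(moments)) {
    stop("need one rotation per atom")
  }
  out <- unclass(moments)
  for (a in seq_len(nrow(moments))) {
    rot <- rotations[[a]]
    if (max(abs(crossprod(rot) - diag(3))) > 1e-10 || det(rot) < 0.5) {
      stop("rotation must be proper and orthogonal")
    }
    for (l in 1:4) {
      sl <- rank_slice(l)
      if (all(moments[a, sl] == 0)) next  # nothing to rotate at this rank
      out[a, sl] <- wigner_real(l, rot) %*% moments[a, sl]
    }
  }
  multipole_set(out, frame = "global")
}

#' Electrostatic interaction energy of two multipole-bearing atoms
#'
#' Sums the spherical-tensor interaction over all rank pairs (l_A, l_B) with
#' both ranks at most `lprime` — a square truncation including e.g. the
#' (3, 3) octupole-octupole term at lprime = 3, not the triangular
#' l_A + l_B + 1 rule.
#'
#' @param momentsA,momentsB length-25 global-frame component vectors (rows
#'   of a global [multipole_set()]).
#' @param rvec separation vector from A to B (Angstrom).
#' @param lprime truncation rank, 0..4.
#' @return energy in kJ/mol.
#' @export
pair_interaction_energy <- function(momentsA, momentsB, rvec, lprime) {
  r <- sqrt(sum(rvec^2))
  if (r <= 0) stop("zero separation")
  Tm <- interaction_matrix(rvec, lprime)
  .COULOMB_KJA * drop(momentsA %*% Tm %*% momentsB)
}

#' Intermolecular multipole electrostatic energy
#'
#' Direct-space sum of [pair_interaction_energy()] over all atom pairs in
#' different molecules separated by at most `cutoff`. Intramolecular pairs
#' are excluded: in this force field the intramolecular electrostatics live
#' inside the machine-learned atomic energies.
#'
#' @param geom a [geometry()] with molecule labels.
#' @param global_moments a global-frame [multipole_set()] (one row per atom).
#' @param lprime truncation rank, 0..4.
#' @param cutoff pair cutoff in Angstrom (default 12).
#' @return energy in kJ/mol.
#' @export
intermolecular_energy <- function(geom, global_moments, lprime, cutoff = 12) {
  if (moment_frame(global_moments) != "global") {
    stop("moments must be in the global frame (see rotate_moments)")
  }
  n <- n_atoms(geom)
  if (length(unique(geom$molecule)) < 2L) {
    warning("single molecule: intermolecular electrostatic energy is 0")
    return(0)
  }
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (geom$molecule[i] == geom$molecule[j]) next
      rvec <- geom$coords[j, ] - geom$coords[i, ]
      if (sqrt(sum(rvec^2)) > cutoff) next
      e <- e + pair_interaction_energy(global_moments[i, ],
                                       global_moments[j, ], rvec, lprime)
    }
  }
  e
}

#' Molecular dipole moment from atomic charges and dipoles
#'
#' mu = sum_A (Q00_A * r_A + mu_A) with mu_A the atomic dipole vector;
#' origin-independent when the net charge vanishes.
#'
#' @param geom a [geometry()].
#' @param global_moments a global-frame [multipole_set()].
#' @return list with `vector_ea` (e*Angstrom, Cartesian), `vector_debye`
#'   and `magnitude_debye`.
#' @export
molecular_dipole <- function(geom, global_moments) {
  if (moment_frame(global_moments) != "global") {
    stop("moments must be in the global frame (see rotate_moments)")
  }
  q <- global_moments[, "Q00"]
  mu_at <- cbind(global_moments[, "Q11"], global_moments[, "Q1m1"],
                 global_moments[, "Q10"])
  v <- colSums(q * geom$coords) + colSums(mu_at)
  list(vector_ea = v, vector_debye = ea_to_debye(v),
       magnitude_debye = ea_to_debye(sqrt(sum(v^2))))
}

#' Convert a charge-prediction error to an interaction-energy error
#'
#' Monopole-monopole energy of a charge error dQ00 (milli-electrons) felt by
#' a probe charge (milli-electrons) at distance R (Angstrom):
#' `1389.35457e-6 * dQ * Qprobe / R` kJ/mol. The worked example
#' (1 me error, 1500 me probe, 2 A) gives 1.0 kJ/mol.
#'
#' @param dq00_me charge error in milli-electrons.
#' @param qprobe_me probing charge in milli-electrons.
#' @param r_ang separation in Angstrom (> 0).
#' @return energy in kJ/mol.
#' @export
charge_error_energy <- function(dq00_me, qprobe_me, r_ang) {
  if (any(r_ang <= 0)) stop("separation must be positive")
  (.COULOMB_KJA * 1e-6) * dq00_me * qprobe_me / r_ang
}

#' Per-pair RMSE heatmap of predicted-moment electrostatic energies
#'
#' For each intermolecular atom pair (i in molecule 1, j in molecule 2) and
#' each validation frame, the pair energy computed from predicted moments is
#' compared with the pair energy from exact moments; the RMSE over frames is
#' reported as a matrix indexed by monomer atom indices.
#'
#' @param geoms list of dimer geometries (consistent atom order).
#' @param predicted,exact lists of global-frame [multipole_set()]s aligned
#'   with `geoms`; `NULL` entries are skipped with a message.
#' @param lprime truncation rank.
#' @return matrix of RMSEs (kJ/mol), rows = molecule-1 atoms, columns =
#'   molecule-2 atoms.
#' @export
electrostatic_error_heatmap <- function(geoms, predicted, exact, lprime) {
  g1 <- geoms[[1]]
  i1 <- which(g1$molecule == g1$molecule[1])
  i2 <- setdiff(seq_len(n_atoms(g1)), i1)
  if (length(i2) == 0) stop("heatmap requires a dimer")
  sq <- matrix(0, length(i1), length(i2))
  nf <- 0L
  for (f in seq_along(geoms)) {
    if (is.null(predicted[[f]]) || is.null(exact[[f]])) {
      message(sprintf("frame %d: missing moments, skipped", f))
      next
    }
    g <- geoms[[f]]
    for (a in seq_along(i1)) {
      for (b in seq_along(i2)) {
        rvec <- g$coords[i2[b], ] - g$coords[i1[a], ]
        ep <- pair_interaction_energy(predicted[[f]][i1[a], ],
                                      predicted[[f]][i2[b], ], rvec, lprime)
        ee <- pair_interaction_energy(exact[[f]][i1[a], ],
                                      exact[[f]][i2[b], ], rvec, lprime)
        sq[a, b] <- sq[a, b] + (ep - ee)^2
      }
    }
    nf <- nf + 1L
  }
  if (nf == 0L) stop("no frames with complete moments")
  out <- sqrt(sq / nf)
  dimnames(out) <- list(paste0(g1$elements[i1], i1),
                        paste0(g1$elements[i2], i2))
  out
}

#' Write an RMSE heatmap matrix as CSV
#' @param heatmap matrix from [electrostatic_error_heatmap()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  utils::write.csv(as.data.frame(heatmap), path, row.names = TRUE)
  invisible(path)
}

#' Realize a pure multipole component as a point-charge array
#'
#' Solves for charges at fixed positions inside a ball of radius `extent`
#' such that all spherical-tensor moments through rank 4 vanish except the
#' requested `(l, m)` component, which equals `value`. Used as an
#' independent oracle for the interaction tensors: the Coulomb energy of two
#' such arrays converges to the pure (l_A, l_B) tensor term as the extent
#' shrinks.
#'
#' @param l,m target component.
#' @param value target moment (e * A^l).
#' @param extent ball radius (Angstrom).
#' @param n_charges number of point charges.
#' @param seed RNG seed for the (fixed) charge positions.
#' @return list with `positions` (n x 3) and `charges`.
#' @export
point_charge_realization <- function(l, m, value = 1, extent = 0.2,
                                     n_charges = 40, seed = 1) {
  set.seed(seed)
  pos <- matrix(stats::rnorm(3 * n_charges), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) *
    (extent * (0.3 + 0.7 * stats::runif(n_charges)))
  lm <- lm_index()
  ## scale rows so the constraint matrix is well conditioned across ranks
  A <- t(vapply(seq_len(nrow(lm)), function(q) {
    p <- sh_poly(lm[q, "l"], lm[q, "m"])
    vapply(seq_len(n_charges), function(s) {
      sum(p[, 4] * pos[s, 1]^p[, 1] * pos[s, 2]^p[, 2] * pos[s, 3]^p[, 3])
    }, numeric(1)) / extent^lm[q, "l"]
  }, numeric(n_charges)))
  b <- numeric(nrow(lm))
  tgt <- which(lm[, "l"] == l & lm[, "m"] == m)
  b[tgt] <- value / extent^l
  ## least-norm solution of the underdetermined system A q = b
  q <- t(A) %*% solve(A %*% t(A), b)
  list(positions = pos, charges = drop(q))
}

#' Coulomb energy between two point-charge arrays
#' @param arrayA,arrayB lists from [point_charge_realization()].
#' @param rvec displacement of array B's origin from array A's.
#' @return energy in kJ/mol.
#' @export
point_charge_energy <- function(arrayA, arrayB, rvec) {
  e <- 0
  for (a in seq_along(arrayA$charges)) {
    d <- t(arrayB$positions) + rvec - arrayA$positions[a, ]
    e <- e + sum(arrayA$charges[a] * arrayB$charges / sqrt(colSums(d^2)))
  }
  .COULOMB_KJA * e
}

#' Write a multipole set as a long-format CSV (atom, l, m, value, frame)
#' @param moments a [multipole_set()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_moment_csv <- function(moments, path) {
  lm <- lm_index()
  tab <- do.call(rbind, lapply(seq_len(nrow(moments)), function(a) {
    data.frame(atom = a, l = lm[, "l"], m = lm[, "m"],
               value = as.numeric(moments[a, ]),
               frame = moment_frame(moments))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format moment CSV back into a multipole set
#' @param path CSV path written by [write_moment_csv()].
#' @return a [multipole_set()].
#' @export
read_moment_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  atoms <- sort(unique(tab$atom))
  mat <- matrix(0, length(atoms), 25)
  lm <- lm_index()
  for (q in seq_len(nrow(tab))) {
    col <- which(lm[, "l"] == tab$l[q] & lm[, "m"] == tab$m[q])
    mat[match(tab$atom[q], atoms), col] <- tab$value[q]
  }
  multipole_set(mat, frame = tab$frame[1])
}
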