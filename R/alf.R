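#' Atomic local frames (ALFs)
#'
#' Each atom A owns a right-handed local frame fixed by two other atoms: the
#' x-axis atom `A_x` (highest priority) and the xy-plane atom `A_xy` (second
#' highest). Priority follows a Cahn-Ingold-Prelog-style rule: neighbour
#' atomic number descending, then extended connectivity (sum of the
#' neighbour's own neighbours' atomic numbers) descending, then atom index
#' ascending as a deterministic tie-break. Neighbours are atoms within
#' 1.2 x the sum of covalent radii; if an atom has fewer than two such
#' neighbours the nearest remaining atoms are used.
#'
#' @name alf
NULL

.BOND_SCALE <- 1.2
.FRAME_SIN_TOL <- 1e-6

bonded_neighbors <- function(geom, i) {
  n <- n_atoms(geom)
  ri <- element_covalent_radius(geom$elements[i])
  d <- sqrt(colSums((t(geom$coords) - geom$coords[i, ])^2))
  rj <- element_covalent_radius(geom$elements)
  cand <- which(d <= .BOND_SCALE * (ri + rj) & seq_len(n) != i &
                  geom$molecule == geom$molecule[i])
  cand
}

#' Assign the atomic local frame of one atom
#'
#' @param geom a [geometry()].
#' @param atom_index origin atom A (1-based).
#' @return a list with `origin`, `ax` (x-axis atom) and `axy` (xy-plane atom).
#' @export
assign_alf <- function(geom, atom_index) {
  n <- n_atoms(geom)
  in_mol <- which(geom$molecule == geom$molecule[atom_index])
  if (length(in_mol) < 3L) {
    stop("no valid ALF: molecule has fewer than 3 atoms")
  }
  cand <- bonded_neighbors(geom, atom_index)
  if (length(cand) < 2L) {
    ## fall back to nearest atoms in the same molecule
    d <- sqrt(colSums((t(geom$coords) - geom$coords[atom_index, ])^2))
    others <- setdiff(in_mol, c(atom_index, cand))
    cand <- c(cand, others[order(d[others])])
  }
  ## extended connectivity: sum of each candidate's neighbours' atomic numbers
  ec <- vapply(cand, function(j) {
    nb <- bonded_neighbors(geom, j)
    if (length(nb) == 0) 0 else sum(geom$number[nb])
  }, numeric(1))
  ord <- order(-geom$number[cand], -ec, cand)
  cand <- cand[ord]
  list(origin = atom_index, ax = cand[1], axy = cand[2])
}

#' Assign ALFs for every atom
#' @param geom a [geometry()].
#' @return list of ALFs, one per atom.
#' @export
alf_list <- function(geom) {
  lapply(seq_len(n_atoms(geom)), function(i) assign_alf(geom, i))
}

## frame axes for atom A: columns ex, ey, ez in the global frame
## (the matrix maps local coordinates to global: r_global = C %*% r_local)
alf_axes <- function(geom, alf) {
  pA <- geom$coords[alf$origin, ]
  u <- geom$coords[alf$ax, ] - pA
  v <- geom$coords[alf$axy, ] - pA
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate ALF: coincident frame atoms")
  sinang <- sqrt(sum(pracma::cross(u, v)^2)) / (nu * nv)
  if (sinang < .FRAME_SIN_TOL) {
    stop("degenerate ALF: frame atoms are collinear")
  }
  ex <- u / nu
  w <- v - sum(v * ex) * ex
  ey <- w / sqrt(sum(w^2))
  ez <- pracma::cross(ex, ey)
  cbind(ex, ey, ez, deparse.level = 0)
}

#' Local-to-global rotation matrix of an atom's ALF
#'
#' Columns are the local x/y/z axes expressed in global coordinates; a
#' local-frame vector `v` maps to the global frame as `R %*% v`.
#'
#' @param geom a [geometry()].
#' @param alf an ALF from [assign_alf()].
#' @return a proper 3 x 3 rotation matrix.
#' @export
alf_rotation <- function(geom, alf) alf_axes(geom, alf)

#' Compute the 3N-6 ALF feature vectors of every atom
#'
#' For atom A with frame atoms `A_x`, `A_xy` the features are: (1) the
#' distance A-A_x, (2) the distance A-A_xy, (3) the valence angle
#' A_x-A-A_xy, then for every remaining atom (in ascending index order) the
#' spherical coordinates (r, theta, phi) in A's local frame. The azimuth phi
#' lies in (-pi, pi] and is flagged cyclic; by convention the mask covers
#' every third feature starting at the third.
#'
#' @param geom a [geometry()] (single molecule; N >= 3).
#' @param alfs list of ALFs, defaults to [alf_list()].
#' @return list with one entry per atom: `values` (length 3N-6), `units`,
#'   `cyclic` (logical mask), `order` (the indices of the "other" atoms, in
#'   feature order) and `alf`.
#' @export
compute_features <- function(geom, alfs = alf_list(geom)) {
  n <- n_atoms(geom)
  if (n < 3L) stop("features require at least 3 atoms")
  lapply(seq_len(n), function(i) {
    alf <- alfs[[i]]
    axes <- alf_axes(geom, alf)
    pA <- geom$coords[alf$origin, ]
    u <- geom$coords[alf$ax, ] - pA
    v <- geom$coords[alf$axy, ] - pA
    f <- numeric(3 * n - 6)
    units <- character(3 * n - 6)
    f[1] <- sqrt(sum(u^2)); units[1] <- "A"
    f[2] <- sqrt(sum(v^2)); units[2] <- "A"
    f[3] <- atan2(sqrt(sum(pracma::cross(u, v)^2)), sum(u * v))
    units[3] <- "rad"
    others <- setdiff(seq_len(n), c(alf$origin, alf$ax, alf$axy))
    k <- 4L
    for (j in others) {
      s <- geom$coords[j, ] - pA
      d <- drop(crossprod(axes, s))
      f[k] <- sqrt(sum(s^2)); units[k] <- "A"
      f[k + 1L] <- atan2(sqrt(d[1]^2 + d[2]^2), d[3]); units[k + 1L] <- "rad"
      f[k + 2L] <- atan2(d[2], d[1]); units[k + 2L] <- "rad"
      k <- k + 3L
    }
    list(values = f, units = units, cyclic = feature_cyclic_mask(n),
         order = others, alf = alf)
  })
}

#' Cyclic mask for a 3N-6 feature vector
#'
#' TRUE for every third feature (indices 3, 6, 9, ...): the azimuthal phi
#' slots plus the third (valence-angle) slot, whose differences never exceed
#' pi so wrapping is the identity there.
#'
#' @param n number of atoms.
#' @return logical vector of length 3N-6.
#' @export
feature_cyclic_mask <- function(n) {
  idx <- seq_len(3 * n - 6)
  idx %% 3L == 0L
}

## forward-mode directional derivative of one atom's features.
## pA,px,pp: frame atom positions; dA,dx,dp their perturbations.
## Returns d(f1,f2,f3) and a function for the (r,theta,phi) block of atom j.
.dnorm3 <- function(x) sqrt(sum(x^2))

alf_dirderiv <- function(pA, px, pp, dA, dx, dp) {
  u <- px - pA; du <- dx - dA
  v <- pp - pA; dv <- dp - dA
  nu <- .dnorm3(u); nv <- .dnorm3(v)
  ex <- u / nu
  dnu <- sum(ex * du)
  dex <- (du - ex * sum(ex * du)) / nu
  dnv <- sum(v * dv) / nv
  ## valence angle via atan2(|u x v|, u.v)
  w <- pracma::cross(u, v)
  dw <- pracma::cross(du, v) + pracma::cross(u, dv)
  s <- .dnorm3(w); c <- sum(u * v)
  ds <- sum(w * dw) / s
  dc <- sum(du * v) + sum(u * dv)
  dang <- (c * ds - s * dc) / (s^2 + c^2)
  ## remaining axes
  wv <- v - sum(v * ex) * ex
  nwv <- .dnorm3(wv)
  ey <- wv / nwv
  dwv <- dv - (sum(dv * ex) + sum(v * dex)) * ex - sum(v * ex) * dex
  dey <- (dwv - ey * sum(ey * dwv)) / nwv
  ez <- pracma::cross(ex, ey)
  dez <- pracma::cross(dex, ey) + pracma::cross(ex, dey)
  list(df123 = c(dnu, dnv, dang),
       ex = ex, ey = ey, ez = ez, dex = dex, dey = dey, dez = dez)
}

spherical_dirderiv <- function(fr, pA, pj, dA, dj) {
  s <- pj - pA; ds <- dj - dA
  r <- .dnorm3(s)
  dr <- sum(s * ds) / r
  d1 <- sum(s * fr$ex); d2 <- sum(s * fr$ey); d3 <- sum(s * fr$ez)
  dd1 <- sum(ds * fr$ex) + sum(s * fr$dex)
  dd2 <- sum(ds * fr$ey) + sum(s * fr$dey)
  dd3 <- sum(ds * fr$ez) + sum(s * fr$dez)
  rho <- sqrt(d1^2 + d2^2)
  drho <- (d1 * dd1 + d2 * dd2) / rho
  dtheta <- (d3 * drho - rho * dd3) / (rho^2 + d3^2)
  dphi <- (d1 * dd2 - d2 * dd1) / (d1^2 + d2^2)
  c(dr, dtheta, dphi)
}

#' Jacobian of every atom's features w.r.t. all Cartesian coordinates
#'
#' Exact forward-mode derivatives of [compute_features()] through the ALF
#' construction. Needed to turn the gradient of a predicted atomic energy in
#' feature space into Cartesian forces: the features of atom A exert a force
#' on every atom B they depend on.
#'
#' @param geom a [geometry()].
#' @param alfs list of ALFs, defaults to [alf_list()].
#' @return list with one (3N-6) x 3N matrix per atom; columns are grouped by
#'   atom as (x1, y1, z1, x2, ...).
#' @export
feature_jacobian <- function(geom, alfs = alf_list(geom)) {
  n <- n_atoms(geom)
  if (n < 3L) stop("features require at least 3 atoms")
  zero <- c(0, 0, 0)
  ident <- diag(3)
  lapply(seq_len(n), function(i) {
    alf <- alfs[[i]]
    pA <- geom$coords[alf$origin, ]
    px <- geom$coords[alf$ax, ]
    pp <- geom$coords[alf$axy, ]
    others <- setdiff(seq_len(n), c(alf$origin, alf$ax, alf$axy))
    J <- matrix(0, 3 * n - 6, 3 * n)
    ## derivative w.r.t. each coordinate of the three frame atoms
    frame_atoms <- c(alf$origin, alf$ax, alf$axy)
    frames <- vector("list", 9L)
    for (a in 1:3) {
      for (ax in 1:3) {
        dA <- if (a == 1) ident[, ax] else zero
        dx <- if (a == 2) ident[, ax] else zero
        dp <- if (a == 3) ident[, ax] else zero
        fr <- alf_dirderiv(pA, px, pp, dA, dx, dp)
        col <- 3L * (frame_atoms[a] - 1L) + ax
        J[1:3, col] <- fr$df123
        frames[[(a - 1L) * 3L + ax]] <- list(fr = fr, col = col, dA = dA)
      }
    }
    ## static frame (no perturbation) for derivatives w.r.t. atom j itself
    fr0 <- alf_dirderiv(pA, px, pp, zero, zero, zero)
    k <- 4L
    for (j in others) {
      pj <- geom$coords[j, ]
      for (entry in frames) {
        J[k:(k + 2L), entry$col] <-
          spherical_dirderiv(entry$fr, pA, pj, entry$dA, zero)
      }
      for (ax in 1:3) {
        col <- 3L * (j - 1L) + ax
        J[k:(k + 2L), col] <-
          spherical_dirderiv(fr0, pA, pj, zero, ident[, ax])
      }
      k <- k + 3L
    }
    J
  })
}

#' Write feature matrices as CSV
#'
#' One row per frame, with header names describing each feature slot of the
#' chosen atom (e.g. `r_C1_O2`, `theta_H5`, `phi_H6`).
#'
#' @param features_list list of per-frame feature sets from
#'   [compute_features()] (all for the same molecule/topology).
#' @param atom atom whose features to tabulate.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features_list, atom, path) {
  f1 <- features_list[[1]][[atom]]
  nm <- c("r_ax", "r_axy", "angle",
          unlist(lapply(f1$order, function(j) {
            sprintf(c("r_%d", "theta_%d", "phi_%d"), j)
          })))
  mat <- t(vapply(features_list, function(fs) fs[[atom]]$values,
                  numeric(length(f1$values))))
  colnames(mat) <- nm
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}

#' Feature matrix of one atom across many geometries
#' @param geoms list of geometries sharing a topology.
#' @param atom atom index.
#' @param alfs optional fixed ALF list (defaults to the first geometry's).
#' @return numeric matrix, one row per geometry.
#' @export
feature_matrix <- function(geoms, atom, alfs = NULL) {
  if (is.null(alfs)) alfs <- alf_list(geoms[[1]])
  t(vapply(geoms, function(g) {
    compute_features(g, alfs)[[atom]]$values
  }, numeric(3 * n_atoms(geoms[[1]]) - 6)))
}

#' Dump ALF assignments as JSON-like text for inspection
#' @param geom a [geometry()].
#' @param alfs list of ALFs, defaults to [alf_list()].
#' @param path optional output file; when `NULL` the text is returned.
#' @return the character vector of lines, invisibly when written to file.
#' @export
write_alf_json <- function(geom, alfs = alf_list(geom), path = NULL) {
  lines <- c("[", paste0(
    vapply(seq_along(alfs), function(i) {
      a <- alfs[[i]]
      sprintf('  {"atom": %d, "element": "%s", "ax": %d, "axy": %d}',
              a$origin, geom$elements[a$origin], a$ax, a$axy)
    }, character(1)),
    c(rep(",", length(alfs) - 1), "")), "]")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
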