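#' Real regular solid harmonics and interaction tensors
#'
#' The electrostatics code is built on Racah-normalised real regular solid
#' harmonics R_lm (R_00 = 1, R_10 = z, R_11 = x, R_1-1 = y,
#' R_20 = (3z^2 - r^2)/2, ...). Rather than transcribing tabulated
#' interaction tensors, everything is generated by exact polynomial algebra:
#'
#' * R_lm polynomial coefficients are recovered by solving the spherical
#'   formula (associated Legendre functions x azimuthal factor) against the
#'   homogeneous monomial basis;
#' * the irregular harmonic I_lm(r) = R_lm(r) / r^(2l+1) gives the potential
#'   of a unit multipole;
#' * the Stone-type interaction tensor T_{l1m1,l2m2}(R) is obtained by
#'   applying the differential operator R_{l2m2}(grad) to I_{l1m1} (exact
#'   differentiation in the ring of polynomial x r^-n terms), normalised by
#'   the Fischer self-product G_lm = [R_lm(grad) R_lm](0);
#' * rank-l real Wigner rotation matrices are recovered numerically from
#'   R_lm(Rot s) expanded in the R_lm' basis.
#'
#' Everything downstream is validated against point-charge arrays.
#'
#' @name solid_harmonics
#' @keywords internal
NULL

.sh_cache <- new.env(parent = emptyenv())

## evaluate R_lm via the spherical formula (pracma::legendre carries the
## Condon-Shortley phase; the (-1)^m factor cancels it)
sh_spherical_eval <- function(l, m, xyz) {
  r <- sqrt(rowSums(xyz^2))
  ct <- xyz[, 3] / r
  phi <- atan2(xyz[, 2], xyz[, 1])
  am <- abs(m)
  if (l == 0) return(rep(1, nrow(xyz)))
  P <- pracma::legendre(l, ct)   # (l+1) x npts, rows m = 0..l
  Plm <- if (is.matrix(P)) P[am + 1L, ] else P[am + 1L]
  norm <- sqrt((2 - (m == 0)) * factorial(l - am) / factorial(l + am))
  azim <- if (m >= 0) cos(am * phi) else sin(am * phi)
  (-1)^am * norm * Plm * azim * r^l
}

## evaluate R_lm at many points from the cached polynomial coefficients
sh_poly_eval <- function(l, m, xyz) {
  p <- sh_poly(l, m)
  out <- numeric(nrow(xyz))
  for (q in seq_len(nrow(p))) {
    out <- out + p[q, 4] * xyz[, 1]^p[q, 1] * xyz[, 2]^p[q, 2] *
      xyz[, 3]^p[q, 3]
  }
  out
}

## monomial exponents (i, j, k) with i + j + k = l
sh_monomials <- function(l) {
  out <- NULL
  for (i in 0:l) for (j in 0:(l - i)) {
    out <- rbind(out, c(i, j, l - i - j))
  }
  out
}

#' Polynomial coefficients of a real regular solid harmonic
#' @param l rank (0..4 used here; any small l works).
#' @param m component, -l..l.
#' @return matrix with columns i, j, k, c: sum of c * x^i y^j z^k.
#' @keywords internal
sh_poly <- function(l, m) {
  key <- sprintf("poly_%d_%d", l, m)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  mono <- sh_monomials(l)
  ## well-spread deterministic sample points
  set.seed(20201L + 7L * l + m)
  npt <- 4L * nrow(mono)
  xyz <- matrix(stats::rnorm(3 * npt), ncol = 3)
  xyz <- xyz / sqrt(rowSums(xyz^2)) * (0.5 + stats::runif(npt))
  A <- vapply(seq_len(nrow(mono)), function(q) {
    xyz[, 1]^mono[q, 1] * xyz[, 2]^mono[q, 2] * xyz[, 3]^mono[q, 3]
  }, numeric(npt))
  b <- sh_spherical_eval(l, m, xyz)
  cf <- qr.solve(A, b)
  cf[abs(cf) < 1e-12] <- 0
  keep <- cf != 0
  out <- cbind(mono[keep, , drop = FALSE], cf[keep])
  colnames(out) <- c("i", "j", "k", "c")
  .sh_cache[[key]] <- out
  out
}

## ---- the ring of sums of c * x^i y^j z^k * r^-n --------------------------
## represented as matrices with columns i, j, k, n, c

rep_simplify <- function(rep) {
  if (nrow(rep) == 0) return(rep)
  key <- paste(rep[, 1], rep[, 2], rep[, 3], rep[, 4])
  c2 <- rowsum(rep[, 5], key)
  first <- rep[!duplicated(key), 1:4, drop = FALSE]
  out <- cbind(first, c2[match(unique(key), rownames(c2)), 1])
  out <- out[abs(out[, 5]) > 1e-14 * max(abs(out[, 5]), 1), , drop = FALSE]
  colnames(out) <- c("i", "j", "k", "n", "c")
  out
}

## d/d(axis) of a rep; axis in 1:3
rep_deriv <- function(rep, axis) {
  p <- rep[, axis]
  out <- NULL
  nz <- p > 0
  if (any(nz)) {
    t1 <- rep[nz, , drop = FALSE]
    t1[, 5] <- t1[, 5] * t1[, axis]
    t1[, axis] <- t1[, axis] - 1
    out <- t1
  }
  nn <- rep[, 4] > 0
  if (any(nn)) {
    t2 <- rep[nn, , drop = FALSE]
    t2[, 5] <- -t2[, 5] * t2[, 4]
    t2[, axis] <- t2[, axis] + 1
    t2[, 4] <- t2[, 4] + 2
    out <- rbind(out, t2)
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 5)
  rep_simplify(out)
}

## apply the differential operator poly(grad) (poly: columns i,j,k,c) to rep
rep_apply_operator <- function(poly, rep) {
  acc <- NULL
  for (q in seq_len(nrow(poly))) {
    r <- rep
    for (ax in 1:3) {
      for (d in seq_len(poly[q, ax])) r <- rep_deriv(r, ax)
    }
    if (nrow(r) > 0) {
      r[, 5] <- r[, 5] * poly[q, 4]
      acc <- rbind(acc, r)
    }
  }
  if (is.null(acc)) acc <- matrix(numeric(0), 0, 5)
  rep_simplify(acc)
}

rep_eval <- function(rep, xyz) {
  if (nrow(rep) == 0) return(0)
  r <- sqrt(sum(xyz^2))
  sum(rep[, 5] * xyz[1]^rep[, 1] * xyz[2]^rep[, 2] * xyz[3]^rep[, 3] *
        r^(-rep[, 4]))
}

## Fischer self-product G_lm = [R_lm(grad) R_lm](0)
sh_fischer_norm <- function(l, m) {
  key <- sprintf("fischer_%d_%d", l, m)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  p <- sh_poly(l, m)
  rep <- cbind(p[, 1:3, drop = FALSE], 0, p[, 4])
  res <- rep_apply_operator(p, rep)
  g <- if (nrow(res) == 0) 0 else res[rowSums(res[, 1:4, drop = FALSE]) == 0, 5]
  if (length(g) != 1 || g <= 0) stop("Fischer norm computation failed")
  .sh_cache[[key]] <- g
  g
}

## component bookkeeping: labels Q00, Q1m1, Q10, Q11, ... map to (l, m)
lm_index <- function() {
  do.call(rbind, lapply(0:4, function(l) cbind(l = l, m = -l:l)))
}

## stacked term table for all interaction tensors with l1, l2 <= lmax.
## Columns: i, j, k, n, c, row (component index of A), col (component of B).
interaction_terms <- function(lmax) {
  key <- sprintf("terms_%d", lmax)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  lm <- lm_index()
  sel <- which(lm[, "l"] <= lmax)
  acc <- vector("list", length(sel)^2)
  q <- 1L
  for (ia in sel) {
    l1 <- lm[ia, "l"]; m1 <- lm[ia, "m"]
    p1 <- sh_poly(l1, m1)
    irep <- cbind(p1[, 1:3, drop = FALSE], 2 * l1 + 1, p1[, 4])
    for (ib in sel) {
      l2 <- lm[ib, "l"]; m2 <- lm[ib, "m"]
      res <- rep_apply_operator(sh_poly(l2, m2), irep)
      if (nrow(res) > 0) {
        res[, 5] <- res[, 5] / sh_fischer_norm(l2, m2)
        acc[[q]] <- cbind(res, row = ia, col = ib)
        q <- q + 1L
      }
    }
  }
  out <- do.call(rbind, acc[seq_len(q - 1L)])
  .sh_cache[[key]] <- out
  out
}

#' Spherical-tensor interaction matrix between two multipole sites
#'
#' Returns the matrix T with entries T\[a, b\] such that the electrostatic
#' interaction energy of global-frame multipole sets QA (at the origin) and
#' QB (at `rvec`) truncated at rank `lprime` on both sites is
#' `C * t(QA) %*% T %*% QB` with C the Coulomb constant in
#' kJ*A/(mol*e^2). Components are ordered Q00, Q1m1, Q10, Q11, ..., Q44.
#'
#' @param rvec separation vector B - A (Angstrom).
#' @param lprime truncation rank, 0..4 (square truncation: all pairs with
#'   both ranks <= lprime).
#' @return a 25 x 25 matrix (entries beyond `lprime` are zero).
#' @export
interaction_matrix <- function(rvec, lprime) {
  stopifnot(length(rvec) == 3, lprime %in% 0:4)
  r <- sqrt(sum(rvec^2))
  if (r <= 0) stop("zero separation between multipole sites")
  tt <- interaction_terms(lprime)
  vals <- tt[, 5] * rvec[1]^tt[, 1] * rvec[2]^tt[, 2] * rvec[3]^tt[, 3] *
    r^(-tt[, 4])
  Tm <- matrix(0, 25, 25)
  idx <- (tt[, 7] - 1L) * 25L + tt[, 6]
  agg <- rowsum(vals, idx)
  Tm[as.integer(rownames(agg))] <- agg[, 1]
  Tm
}

## ---- real Wigner rotation matrices ---------------------------------------

wigner_sample_points <- function(l) {
  key <- sprintf("wpts_%d", l)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  set.seed(4242L + l)
  npt <- 2L * (2L * l + 1L)
  pts <- matrix(stats::rnorm(3 * npt), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (0.8 + 0.4 * stats::runif(npt))
  B <- vapply(-l:l, function(m) sh_poly_eval(l, m, pts), numeric(npt))
  out <- list(pts = pts, qrB = qr(B))
  .sh_cache[[key]] <- out
  out
}

#' Rank-l real Wigner rotation matrix
#'
#' The matrix M with `R_lm(Rot s) = sum_m' M[m, m'] R_lm'(s)`; global-frame
#' moments of a rotated density are `M %*% Q_local`.
#'
#' @param l rank.
#' @param rot proper 3 x 3 rotation matrix (local -> global).
#' @return (2l+1) x (2l+1) orthogonal matrix, components ordered m = -l..l.
#' @export
wigner_real <- function(l, rot) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) {
    ## components are ordered (y, z, x): conjugate the Cartesian rotation
    P <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))  # (y,z,x) -> (x,y,z)
    return(t(P) %*% rot %*% P)
  }
  sp <- wigner_sample_points(l)
  rotated <- sp$pts %*% t(rot)   # rows Rot %*% p
  E <- vapply(-l:l, function(m) sh_poly_eval(l, m, rotated),
              numeric(nrow(sp$pts)))
  t(qr.coef(sp$qrB, E))
}
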