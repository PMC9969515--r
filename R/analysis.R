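#' Validation analytics
#'
#' S-curves (cumulative error distributions), Kabsch superposition RMSD,
#' dimer classification against reference structures, hydrogen-bond
#' geometry tables, bond-length-change reports and energy rankings.
#'
#' @name analysis
NULL

#' Per-frame prediction errors
#'
#' `mode = "cancel"`: absolute difference of the summed (molecular)
#' property, allowing per-atom errors to cancel; `mode = "sum-abs"`: sum of
#' absolute per-atom errors; `mode = "per-atom"`: the full matrix of
#' absolute per-atom errors.
#'
#' @param true,predicted numeric matrices (frames x atoms) or vectors.
#' @param mode one of `"cancel"`, `"sum-abs"`, `"per-atom"`.
#' @return numeric vector per frame (or matrix for `"per-atom"`).
#' @export
prediction_errors <- function(true, predicted,
                              mode = c("cancel", "sum-abs", "per-atom")) {
  mode <- match.arg(mode)
  true <- as.matrix(true); predicted <- as.matrix(predicted)
  if (!all(dim(true) == dim(predicted))) {
    stop("true and predicted records are misaligned")
  }
  switch(mode,
         "cancel" = abs(rowSums(true) - rowSums(predicted)),
         "sum-abs" = rowSums(abs(true - predicted)),
         "per-atom" = abs(true - predicted))
}

#' Build an S-curve from absolute errors
#'
#' Errors sorted ascending against the inclusive percentile `100 * i / n`;
#' the cumulative distribution crosses 50% at the median and reaches 100%
#' at the maximum error.
#'
#' @param errors nonnegative errors (any unit).
#' @return object of class `s_curve`: data.frame with `error` and
#'   `percentile`.
#' @export
s_curve <- function(errors) {
  if (length(errors) == 0) stop("no errors supplied")
  if (any(errors < 0)) stop("S-curves expect absolute (nonnegative) errors")
  e <- sort(errors)
  structure(data.frame(error = e,
                       percentile = 100 * seq_along(e) / length(e)),
            class = c("s_curve", "data.frame"))
}

#' Quantile lookup on an S-curve
#' @param sc an `s_curve`.
#' @param percentile percentile(s) in (0, 100].
#' @return the smallest error whose percentile reaches the target.
#' @export
s_curve_quantile <- function(sc, percentile) {
  vapply(percentile, function(p) {
    if (p <= 0 || p > 100) stop("percentile must be in (0, 100]")
    sc$error[which(sc$percentile >= p)[1]]
  }, numeric(1))
}

#' Kabsch-superposed RMSD between two geometries
#'
#' Minimal root-mean-square deviation over proper rotations and
#' translations (reflections excluded by the determinant correction), with
#' atom correspondence taken from the atom order.
#'
#' @param geomA,geomB geometries with equal atom counts.
#' @return list with `rmsd` (A), `rotation` (applied to centered B to best
#'   match centered A) and `translation` components `centroidA`,
#'   `centroidB`.
#' @export
kabsch_rmsd <- function(geomA, geomB) {
  A <- geomA$coords; B <- geomB$coords
  if (nrow(A) != nrow(B)) stop("atom-count mismatch")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))   # H = B0' A0
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)     # rotation applied to B0 rows: B0 %*% t(R)
  diff <- A0 - B0 %*% t(R)
  list(rmsd = sqrt(mean(rowSums(diff^2))), rotation = R,
       translation = list(centroidA = ca, centroidB = cb))
}

#' Classify an optimized dimer against labelled references
#'
#' Returns the label of the minimum-RMSD reference if that RMSD is below
#' the threshold, else `"unmatched"`. Because random-start optimizations
#' can land with the two monomers swapped, the swapped atom correspondence
#' (molecule 1 <-> molecule 2) is also tried and the lower RMSD kept.
#'
#' @param optimized a dimer [geometry()].
#' @param references named list of reference dimer geometries.
#' @param threshold match threshold in Angstrom (default 0.2).
#' @param try_swap also try the monomer-swapped correspondence (default
#'   TRUE; requires equal monomer sizes).
#' @return list with `label`, `rmsd`, and the per-reference `rmsds`.
#' @export
classify_dimer <- function(optimized, references, threshold = 0.2,
                           try_swap = TRUE) {
  if (length(references) == 0) stop("no reference structures")
  n <- n_atoms(optimized)
  half <- n %/% 2
  swapped <- NULL
  if (try_swap && 2 * half == n) {
    perm <- c((half + 1):n, 1:half)
    swapped <- geometry(optimized$elements[perm],
                        optimized$coords[perm, , drop = FALSE],
                        molecule = optimized$molecule)
  }
  rmsds <- vapply(references, function(ref) {
    if (n_atoms(ref) != n) stop("atom-count mismatch with a reference")
    r1 <- kabsch_rmsd(ref, optimized)$rmsd
    r2 <- if (!is.null(swapped) &&
                all(swapped$elements == ref$elements)) {
      kabsch_rmsd(ref, swapped)$rmsd
    } else Inf
    min(r1, r2)
  }, numeric(1))
  best <- which.min(rmsds)   # ties: first label in list order
  if (rmsds[best] < threshold) {
    list(label = names(references)[best], rmsd = rmsds[best], rmsds = rmsds)
  } else {
    list(label = "unmatched", rmsd = rmsds[best], rmsds = rmsds)
  }
}

#' Hydrogen-bond geometry table
#'
#' For declared donor-H...acceptor triples: the H...acceptor distance, the
#' donor-H...acceptor angle, and optionally the angle at the acceptor to a
#' fourth (antecedent) atom, e.g. C=O...H.
#'
#' @param geom a [geometry()].
#' @param triples data.frame with columns `donor`, `h`, `acceptor` and
#'   optionally `antecedent` (NA where unused).
#' @return data.frame with distances (A) and angles (degrees).
#' @export
hbond_report <- function(geom, triples) {
  n <- n_atoms(geom)
  idx <- unlist(triples[c("donor", "h", "acceptor")])
  if (any(idx < 1 | idx > n)) stop("hbond triple index out of range")
  deg <- 180 / pi
  out <- lapply(seq_len(nrow(triples)), function(q) {
    t <- triples[q, ]
    d <- geom$coords[t$donor, ]; h <- geom$coords[t$h, ]
    a <- geom$coords[t$acceptor, ]
    ang_ant <- NA_real_
    if (!is.null(t$antecedent) && !is.na(t$antecedent)) {
      x <- geom$coords[t$antecedent, ]
      ang_ant <- deg * vec_angle(x - a, h - a)
    }
    data.frame(
      donor = t$donor, h = t$h, acceptor = t$acceptor,
      h_acceptor_dist = sqrt(sum((a - h)^2)),
      donor_h_acceptor_angle = deg * vec_angle(d - h, a - h),
      antecedent_angle = ang_ant)
  })
  do.call(rbind, out)
}

#' Bond-length changes of dimer halves relative to a monomer reference
#'
#' For each dimer and each listed bond: `length(dimer) - length(monomer)`
#' in Angstrom (negative = shortening), reported at 3 decimals in the
#' `delta` column with the raw difference kept in `delta_raw`. Bond
#' indices refer to the monomer; `half` selects which monomer copy in the
#' dimer (1-based block).
#'
#' @param monomer_ref monomer reference [geometry()].
#' @param dimers named list of dimer geometries.
#' @param bonds data.frame with columns `i`, `j` (monomer atom indices),
#'   optional `label` and `half` (default 1).
#' @return data.frame with one row per dimer x bond.
#' @export
bond_change_report <- function(monomer_ref, dimers, bonds) {
  nm <- n_atoms(monomer_ref)
  if (is.null(bonds$half)) bonds$half <- 1L
  if (is.null(bonds$label)) {
    bonds$label <- paste0(monomer_ref$elements[bonds$i], bonds$i, "-",
                          monomer_ref$elements[bonds$j], bonds$j)
  }
  if (any(bonds$i > nm | bonds$j > nm)) stop("bond index out of range")
  blen <- function(g, i, j) sqrt(sum((g$coords[j, ] - g$coords[i, ])^2))
  ref_len <- mapply(function(i, j) blen(monomer_ref, i, j),
                    bonds$i, bonds$j)
  out <- lapply(seq_along(dimers), function(d) {
    g <- dimers[[d]]
    off <- (bonds$half - 1L) * nm
    if (any(off + pmax(bonds$i, bonds$j) > n_atoms(g))) {
      stop("bond index out of range in dimer ", names(dimers)[d])
    }
    len <- mapply(function(i, j) blen(g, i, j), bonds$i + off,
                  bonds$j + off)
    data.frame(dimer = names(dimers)[d], bond = bonds$label,
               monomer = ref_len, dimer_length = len,
               delta = round(len - ref_len, 3), delta_raw = len - ref_len)
  })
  do.call(rbind, out)
}

#' Rank labelled energies
#'
#' Ascending energy order with relative energies against the minimum; ties
#' break by label order (stable).
#'
#' @param energies named numeric vector (>= 2 entries, unique labels).
#' @return data.frame with `label`, `energy`, `relative` ordered by energy.
#' @export
energy_ranking <- function(energies) {
  if (length(energies) < 2) stop("need at least 2 energies to rank")
  if (is.null(names(energies)) || anyDuplicated(names(energies))) {
    stop("energies must carry unique labels")
  }
  ord <- order(energies, names(energies))
  data.frame(label = names(energies)[ord], energy = energies[ord],
             relative = energies[ord] - min(energies), row.names = NULL)
}

#' Write an S-curve as CSV (error, percentile)
#' @param sc an `s_curve`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_s_curve_csv <- function(sc, path) {
  utils::write.csv(as.data.frame(sc), path, row.names = FALSE)
  invisible(path)
}

#' Plot an S-curve (log-x cumulative error distribution)
#' @param sc an `s_curve`.
#' @return a ggplot object.
#' @export
plot_s_curve <- function(sc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_s_curve needs ggplot2")
  }
  ggplot2::ggplot(as.data.frame(sc),
                  ggplot2::aes(x = error, y = percentile)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "absolute error", y = "percentile") +
    ggplot2::theme_minimal()
}

#' Plot a per-pair electrostatic RMSE heatmap
#' @param heatmap matrix from [electrostatic_error_heatmap()].
#' @return a ggplot object.
#' @export
plot_error_heatmap <- function(heatmap) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_error_heatmap needs ggplot2")
  }
  df <- expand.grid(atom1 = rownames(heatmap), atom2 = colnames(heatmap),
                    stringsAsFactors = FALSE)
  df$rmse <- as.vector(heatmap)
  ggplot2::ggplot(df, ggplot2::aes(x = atom2, y = atom1, fill = rmse)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "molecule 2 atom", y = "molecule 1 atom",
                  fill = "RMSE (kJ/mol)") +
    ggplot2::theme_minimal()
}
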