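#' Molecular geometries
#'
#' A `geometry` is an ordered set of atoms: element symbols, atomic numbers
#' and Cartesian coordinates in Angstrom, with an optional `molecule` label
#' vector partitioning atoms into molecules (contiguous blocks; no bond
#' perception is attempted). Atom order is significant: features, Jacobians
#' and RMSD all depend on it.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param molecule optional integer vector of molecule ids (length N).
#' @param comment optional free-text metadata (e.g. an XYZ comment line).
#' @return an object of class `geometry`.
#' @export
geometry <- function(elements, coords, molecule = NULL, comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  if (n < 1L) stop("geometry needs at least one atom")
  if (nrow(coords) != n) stop("elements and coords disagree on atom count")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  number <- element_number(elements)  # errors on unknown symbols
  if (is.null(molecule)) molecule <- rep(1L, n)
  if (length(molecule) != n) stop("molecule labels must cover every atom")
  structure(
    list(elements = as.character(elements), number = number,
         coords = coords, molecule = as.integer(molecule),
         comment = as.character(comment)[1]),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms, %d molecule(s)\n",
              n_atoms(x), length(unique(x$molecule))))
  for (i in seq_len(min(n_atoms(x), 12L))) {
    cat(sprintf("  %-2s %10.5f %10.5f %10.5f\n", x$elements[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  }
  if (n_atoms(x) > 12L) cat("  ...\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) nrow(geom$coords)

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: per frame, an atom-count line, a comment line, then one
#' `symbol x y z` line per atom. The comment line is retained as metadata.
#'
#' @param path file path.
#' @param molecule optional molecule-id vector applied to every frame.
#' @return a list of `geometry` objects, one per frame, in file order.
#' @export
read_xyz <- function(path, molecule = NULL) {
  lines <- readLines(path)
  ## drop trailing blank lines only
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("line %d: frame declares %d atoms but file ends early",
                   i, nat))
    }
    comment <- lines[i + 1L]
    elements <- character(nat)
    coords <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L) {
        stop(sprintf("line %d: malformed atom line '%s'", ln, lines[ln]))
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) {
        stop(sprintf("line %d: non-numeric coordinates in '%s'", ln, lines[ln]))
      }
      elements[a] <- tok[1]
      coords[a, ] <- xyz
    }
    frames[[length(frames) + 1L]] <-
      geometry(elements, coords, molecule = molecule, comment = comment)
    i <- i + 2L + nat
  }
  frames
}

#' Write geometries to a multi-frame XYZ file
#'
#' Coordinates are written with enough digits that a read/write round trip
#' is lossless to well below 1e-9 Angstrom.
#'
#' @param geometries a `geometry` or list of geometries.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometries, path) {
  if (inherits(geometries, "geometry")) geometries <- list(geometries)
  if (length(geometries) == 0L) {
    warning("writing an empty XYZ file (no geometries)")
    cat("", file = path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geometries) {
    writeLines(as.character(n_atoms(g)), con)
    writeLines(if (nzchar(g$comment)) g$comment else "", con)
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", g$elements,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

## ---- per-atom property records ------------------------------------------

moment_labels <- function() {
  unlist(lapply(0:4, function(l) {
    m <- -l:l
    sprintf("Q%d%s", l, ifelse(m < 0, paste0("m", -m), as.character(m)))
  }))
}

#' Read a per-atom property table
#'
#' Tabular (CSV) training targets keyed by `(frame, atom)`: the atomic energy
#' (kJ/mol, column `energy`) and the 25 real spherical-tensor moment
#' components `Q00, Q1m1, Q10, Q11, ..., Q44` (e for l = 0, e*A^l above),
#' expressed in each atom's local frame. Extra columns (IQA sub-terms etc.)
#' are passed through untouched.
#'
#' @param path CSV path.
#' @return a data.frame with at least `frame`, `atom`, `energy` and the 25
#'   moment columns.
#' @export
read_property_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "energy", moment_labels())
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("property table missing column(s): ", paste(miss, collapse = ", "))
  }
  num <- setdiff(need, c("frame", "atom"))
  if (!all(vapply(tab[num], function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite energies or moments in property table")
  }
  tab
}

#' Write a per-atom property table
#' @param tab data.frame as returned by [read_property_table()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

## ---- Lennard-Jones parameter tables -------------------------------------

#' Lennard-Jones parameters per atom type
#'
#' @param type character atom-type labels (element symbols by default).
#' @param epsilon well depths, kJ/mol (>= 0).
#' @param sigma zero-crossing distances, Angstrom (> 0).
#' @return a data.frame of class `lj_params` with Lorentz-Berthelot combining.
#' @export
lj_params <- function(type, epsilon, sigma) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(type)) stop("duplicate atom types in LJ table")
  structure(data.frame(type = as.character(type), epsilon = epsilon,
                       sigma = sigma, stringsAsFactors = FALSE),
            class = c("lj_params", "data.frame"),
            combining = "lorentz-berthelot")
}

#' Read a Lennard-Jones parameter table (CSV: type, epsilon, sigma)
#' @param path CSV path.
#' @return an `lj_params` table.
#' @export
read_lj_params <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "epsilon", "sigma")
  if (!all(need %in% names(tab))) {
    stop("LJ table must have columns type, epsilon, sigma")
  }
  lj_params(tab$type, tab$epsilon, tab$sigma)
}

## ---- run configuration ---------------------------------------------------

#' Read a run configuration file (YAML)
#'
#' Recognised keys (all optional, with defaults): `level_of_theory` (free
#' tag), `lprime` (multipole truncation rank, 0-4), `cutoff` (A),
#' `timestep` (fs), `lj_table` (path), `seed`, `box` (A, non-periodic
#' extent). Unknown keys are kept.
#'
#' @param path YAML file path.
#' @return a named list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(level_of_theory = "surrogate", lprime = 3L, cutoff = 12,
                   timestep = 1, lj_table = NULL, seed = 1L, box = 50)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (!cfg$lprime %in% 0:4) stop("lprime must be an integer in 0..4")
  if (cfg$cutoff <= 0) stop("cutoff must be positive")
  if (cfg$timestep <= 0) stop("timestep must be positive")
  cfg
}
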