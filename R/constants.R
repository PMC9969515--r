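#' Physical constants and unit conversions
#'
#' Internal units are kJ/mol for energy, Angstrom for length, elementary
#' charges for charge (moments in e*A^l), femtoseconds for time and g/mol for
#' mass. These constants bridge to external conventions.
#'
#' @name units
NULL

## CODATA-derived conversion factors
.HARTREE_KJMOL <- 2625.4996          # kJ/mol per hartree
.COULOMB_KJA <- 1389.35457           # kJ*A/(mol*e^2): q1*q2/r -> kJ/mol
.EA_TO_DEBYE <- 4.8032047            # Debye per e*Angstrom
.KB_KJMOL <- 0.008314462618          # kJ/(mol*K)
## acceleration: (kJ/mol/A) / (g/mol) expressed in A/fs^2
.ACC_UNIT <- 1e-4
## speed: sqrt(kJ/mol / (g/mol)) = 1000 m/s, expressed in A/fs
.SPEED_UNIT <- 1e-2

#' Convert hartree to kJ/mol
#'
#' Linear unit bridge for energies produced by external quantum-chemistry
#' codes; all internal energies are kJ/mol.
#'
#' @param x numeric vector of energies in hartree.
#' @return energies in kJ/mol.
#' @examples
#' hartree_to_kjmol(1)     # 2625.4996
#' @export
hartree_to_kjmol <- function(x) {
  stopifnot(is.numeric(x))
  x * .HARTREE_KJMOL
}

#' Convert kJ/mol to hartree
#' @param x numeric vector of energies in kJ/mol.
#' @return energies in hartree.
#' @export
kjmol_to_hartree <- function(x) {
  stopifnot(is.numeric(x))
  x / .HARTREE_KJMOL
}

#' Convert a dipole in e*Angstrom to Debye
#' @param x numeric dipole (components or magnitude) in e*A.
#' @return value in Debye.
#' @export
ea_to_debye <- function(x) x * .EA_TO_DEBYE

## element data: atomic numbers, masses (g/mol), covalent radii (A)
.ELEMENTS <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I"),
  number = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
             11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 35, 53),
  mass = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
           18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
           35.45, 39.948, 39.098, 40.078, 79.904, 126.90),
  covalent_radius = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57,
                      0.58, 1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06,
                      2.03, 1.76, 1.20, 1.39),
  stringsAsFactors = FALSE
)

element_number <- function(symbol) {
  idx <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .ELEMENTS$number[idx]
}

element_mass <- function(symbol) {
  .ELEMENTS$mass[match(symbol, .ELEMENTS$symbol)]
}

element_covalent_radius <- function(symbol) {
  .ELEMENTS$covalent_radius[match(symbol, .ELEMENTS$symbol)]
}

## non-standard-evaluation columns used in ggplot calls
utils::globalVariables(c("error", "percentile", "atom1", "atom2", "rmse"))
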