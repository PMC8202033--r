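#' @useDynLib hirshfeldr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Physical constants (CODATA-style values; the kJ/mol conversion is fixed
## here and used everywhere energies are reported).
BOHR_TO_ANGSTROM <- 0.52917721067
ANGSTROM_TO_BOHR <- 1 / BOHR_TO_ANGSTROM
HARTREE_TO_KJMOL <- 2625.499639
## Coulomb constant q1*q2/r for unit charges in e, r in Angstrom -> kJ/mol
COULOMB_KJMOL_ANG <- HARTREE_TO_KJMOL * BOHR_TO_ANGSTROM

ELEMENT_SYMBOLS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

## Covalent radii in Angstrom (Cordero et al. consensus values; Mn/Fe/Co low
## spin).  Used only for bond perception.
COVALENT_RADII <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16
)

## van der Waals radii in Angstrom: Bondi values with the 1.09 A variant for
## H conventional in crystal-contact analysis.  Sc-Fe are not in Bondi's
## table; generic placeholders there (flagged, rarely used for d_norm).
VDW_RADII <- c(
  H = 1.09, He = 1.40,
  Li = 1.81, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Ar = 1.88,
  K = 2.75, Ca = 2.31, Sc = 2.15, Ti = 2.11, V = 2.07, Cr = 2.06, Mn = 2.05,
  Fe = 2.04, Co = 2.00, Ni = 1.63, Cu = 1.40, Zn = 1.39,
  Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02
)

## Grimme D2 dispersion parameters: C6 in J nm^6 mol^-1, R0 (vdW) in
## Angstrom, damping steepness d = 20.  The global s6 scaling is NOT applied
## here; the interaction-energy model's own k_dis plays that role.
D2_C6 <- c(
  H = 0.14, He = 0.08,
  Li = 1.61, Be = 1.61, B = 3.13, C = 1.75, N = 1.23, O = 0.70, F = 0.75,
  Ne = 0.63,
  Na = 5.71, Mg = 5.71, Al = 10.79, Si = 9.23, P = 7.84, S = 5.57,
  Cl = 5.07, Ar = 4.61,
  K = 10.80, Ca = 10.80, Sc = 10.80, Ti = 10.80, V = 10.80, Cr = 10.80,
  Mn = 10.80, Fe = 10.80, Co = 10.80, Ni = 10.80, Cu = 10.80, Zn = 10.80,
  Ga = 16.99, Ge = 17.10, As = 16.37, Se = 12.64, Br = 12.47, Kr = 12.01
)
D2_R0 <- c(
  H = 1.001, He = 1.012,
  Li = 0.825, Be = 1.408, B = 1.485, C = 1.452, N = 1.397, O = 1.342,
  F = 1.287, Ne = 1.243,
  Na = 1.144, Mg = 1.364, Al = 1.639, Si = 1.716, P = 1.705, S = 1.683,
  Cl = 1.639, Ar = 1.595,
  K = 1.485, Ca = 1.474, Sc = 1.562, Ti = 1.562, V = 1.562, Cr = 1.562,
  Mn = 1.562, Fe = 1.562, Co = 1.562, Ni = 1.562, Cu = 1.562, Zn = 1.562,
  Ga = 1.650, Ge = 1.727, As = 1.760, Se = 1.771, Br = 1.749, Kr = 1.727
)
D2_DAMPING_D <- 20

## Isotropic free-atom static dipole polarizabilities in atomic units
## (standard compiled recommended values); used by the polarization term.
ATOMIC_POLARIZABILITY <- c(
  H = 4.50, He = 1.38,
  Li = 164.1, Be = 37.7, B = 20.5, C = 11.3, N = 7.4, O = 5.3, F = 3.74,
  Ne = 2.66,
  Na = 162.7, Mg = 71.2, Al = 57.8, Si = 37.3, P = 25.0, S = 19.4,
  Cl = 14.6, Ar = 11.08,
  K = 289.7, Ca = 160.8, Sc = 97.0, Ti = 100.0, V = 87.0, Cr = 83.0,
  Mn = 68.0, Fe = 62.0, Co = 57.0, Ni = 51.0, Cu = 46.5, Zn = 38.7,
  Ga = 50.0, Ge = 40.0, As = 30.0, Se = 28.9, Br = 21.0, Kr = 16.8
)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (H through Kr).
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- match(element, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unsupported element(s): ", paste(unique(element[is.na(z)]), collapse = ", "),
         "; supported: ", paste(ELEMENT_SYMBOLS, collapse = " "))
  }
  z
}

check_elements <- function(element) invisible(atomic_number(element))

element_property <- function(element, table, what) {
  check_elements(element)
  v <- unname(table[element])
  if (anyNA(v)) stop("no ", what, " for element(s): ",
                     paste(unique(element[is.na(v)]), collapse = ", "))
  v
}

#' Covalent radius lookup (Angstrom)
#' @inheritParams atomic_number
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) element_property(element, COVALENT_RADII, "covalent radius")

#' van der Waals radius lookup (Angstrom)
#'
#' Bondi radii with the 1.09 Angstrom variant for hydrogen, the convention
#' used for normalized contact distances on Hirshfeld surfaces.
#' @inheritParams atomic_number
#' @return Numeric vector of van der Waals radii in Angstrom.
#' @export
vdw_radius <- function(element) element_property(element, VDW_RADII, "vdW radius")
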