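# Static physicochemical element data used across the package:
# covalent radii (bond perception, PQR radii, geometric damping),
# Pauling electronegativities (MGC), valence-electron counts (VEEM).

#' @keywords internal
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

# Single-bond covalent radii in Angstrom (Cordero et al. 2008,
# Dalton Trans. 2832; low-spin values for Mn/Fe/Co, sp3 carbon).
.covalent_radius <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03,
  Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16, Rb = 2.20,
  Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54, Tc = 1.47,
  Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44, In = 1.42,
  Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40, Cs = 2.44,
  Ba = 2.15, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41, Pt = 1.36,
  Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46, Bi = 1.48, U = 1.96)

# Pauling-scale electronegativities for the elements that commonly occur
# in organic and biomolecular structures.
.pauling_en <- c(
  H = 2.20, Li = 0.98, Be = 1.57, B = 2.04, C = 2.55, N = 3.04, O = 3.44,
  F = 3.98, Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90, P = 2.19,
  S = 2.58, Cl = 3.16, K = 0.82, Ca = 1.00, Sc = 1.36, Ti = 1.54,
  V = 1.63, Cr = 1.66, Mn = 1.55, Fe = 1.83, Co = 1.88, Ni = 1.91,
  Cu = 1.90, Zn = 1.65, Ga = 1.81, Ge = 2.01, As = 2.18, Se = 2.55,
  Br = 2.96, Rb = 0.82, Sr = 0.95, Mo = 2.16, Ru = 2.20, Rh = 2.28,
  Pd = 2.20, Ag = 1.93, Cd = 1.69, Sn = 1.96, Sb = 2.05, Te = 2.10,
  I = 2.66, Cs = 0.79, Ba = 0.89, W = 2.36, Pt = 2.28, Au = 2.54,
  Hg = 2.00, Tl = 1.62, Pb = 2.33, Bi = 2.02)

# Valence (outer-shell) electron counts; main-group values follow the
# group number, transition metals count the ns electrons plus (n-1)d.
.valence_electrons <- c(
  H = 1, He = 2, Li = 1, Be = 2, B = 3, C = 4, N = 5, O = 6, F = 7,
  Ne = 8, Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2, Sc = 3, Ti = 4, V = 5, Cr = 6, Mn = 7, Fe = 8, Co = 9,
  Ni = 10, Cu = 11, Zn = 12, Ga = 3, Ge = 4, As = 5, Se = 6, Br = 7,
  Kr = 8, Rb = 1, Sr = 2, Ag = 11, Cd = 12, In = 3, Sn = 4, Sb = 5,
  Te = 6, I = 7, Xe = 8, Cs = 1, Ba = 2)

#' Covalent radius of an element
#'
#' Single-bond covalent radii (Cordero et al. 2008) in Angstrom, used for
#' distance-based bond perception, PQR radius columns and geometry-damped
#' charge transfer.  Unknown elements fall back to 1.5 A with a warning.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
#' @examples
#' covalent_radius(c("C", "H", "O"))
covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  if (anyNA(r)) {
    warning("no covalent radius tabulated for: ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using 1.5 A")
    r[is.na(r)] <- 1.5
  }
  unname(r)
}

is_valid_element <- function(element) {
  element %in% .element_symbols
}

pauling_electronegativity <- function(element) {
  x <- .pauling_en[element]
  if (anyNA(x)) {
    stop("no electronegativity tabulated for element(s): ",
         paste(unique(element[is.na(x)]), collapse = ", "))
  }
  unname(x)
}

valence_electron_count <- function(element) {
  v <- .valence_electrons[element]
  if (anyNA(v)) {
    stop("no valence-electron count tabulated for element(s): ",
         paste(unique(element[is.na(v)]), collapse = ", "))
  }
  unname(v)
}

# Coulomb constant in eV * A / e^2.
.k_coulomb <- 14.399645

# Normalise an element symbol coming from a file (e.g. "CL", "ca") to
# periodic-table capitalisation.
normalize_element <- function(x) {
  x <- trimws(x)
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
  x
}
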