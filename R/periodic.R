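# Element symbols and standard atomic weights for Z = 1..100.
# Weights beyond Z = 96 are the mass numbers of the most stable isotopes.

.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm")

.ATOMIC_WEIGHTS <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 97, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222, 223, 226, 227, 232.04,
  231.04, 238.03, 237, 244, 243, 247, 247, 251, 252, 257)

# Default valences of the neutral elements the implicit-hydrogen model
# supports; elements not listed get 0 implicit hydrogens.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 4, P = 3, S = 2, Cl = 1, Br = 1, I = 1)

# Single-bond covalent radii (Angstrom) for the supported organic set;
# elements not listed use the fallback radius.
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20,
  I = 1.39)
.COVALENT_RADIUS_DEFAULT <- 1.2

#' Atomic number of an element symbol
#'
#' @param symbol Character vector of element symbols (case sensitive, e.g.
#'   \code{"Cl"}).
#' @return Integer vector of nuclear charges; 0 for unknown symbols.
#' @examples
#' atomicNumber(c("C", "N", "Cl"))
#' @export
atomicNumber <- function(symbol) {
  z <- match(symbol, .ELEMENT_SYMBOLS)
  z[is.na(z)] <- 0L
  as.integer(z)
}
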