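## Physical constants and per-element data.  All internal math is in
## atomic units (bohr, hartree); file I/O and user-facing lengths are in
## Angstrom, pressures in GPa.

#' Unit conversion constants
#'
#' Fixed conversion factors used throughout: `bohr_per_angstrom`
#' (1 Angstrom = 1.8897261246 bohr), `gpa_per_au` (1 hartree/bohr^3 =
#' 29421.0265 GPa) and `kjmol_per_hartree` (1 hartree = 2625.4996 kJ/mol).
#'
#' @name units
#' @keywords internal
NULL

bohr_per_angstrom <- 1.8897261246
gpa_per_au <- 29421.0265
kjmol_per_hartree <- 2625.4996

## atomic numbers and Bondi van der Waals radii (Angstrom)
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "P", "S", "Cl", "Ar"),
  Z = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 15, 16, 17, 18),
  r_vdw = c(1.20, 1.40, 1.82, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
            2.27, 1.73, 1.80, 1.80, 1.75, 1.88),
  stringsAsFactors = FALSE
)

element_number <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("unknown element(s): ", paste(symbol[is.na(i)], collapse = ", "))
  .element_table$Z[i]
}

#' Default van der Waals radii
#'
#' Bondi van der Waals radii in Angstrom for the supported elements, used
#' as default cavity sphere radii unless overridden.
#'
#' @param symbol character vector of element symbols.
#' @return named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("no van der Waals radius for element(s): ",
                     paste(symbol[is.na(i)], collapse = ", "))
  stats::setNames(.element_table$r_vdw[i], symbol)
}
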