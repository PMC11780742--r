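## Molecular geometry container and XYZ file I/O.

#' Create a molecule
#'
#' Builds the geometry object used by all other functions.  Coordinates
#' are given in Angstrom and stored internally in bohr.  Ghost atoms carry
#' basis functions but no nuclear charge and no cavity sphere; they are
#' used by the counterpoise protocol.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom.
#' @param ghost logical vector marking ghost atoms (default none).
#' @param charge total molecular charge.
#' @return an object of class `hipres_mol`.
#' @export
molecule <- function(symbols, coords, ghost = rep(FALSE, length(symbols)), charge = 0) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == length(symbols), length(ghost) == length(symbols))
  Z <- element_number(symbols)
  structure(list(
    symbols = symbols,
    xyz = coords * bohr_per_angstrom,  # bohr
    Z = ifelse(ghost, 0, Z),
    Zel = Z,                            # element identity (also for ghosts)
    ghost = ghost,
    charge = charge
  ), class = "hipres_mol")
}

#' @export
print.hipres_mol <- function(x, ...) {
  cat(sprintf("<hipres_mol> %d atoms (%d ghost), charge %d, %d electrons\n",
              length(x$symbols), sum(x$ghost), x$charge, n_electrons(x)))
  ang <- x$xyz / bohr_per_angstrom
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-2s%s %12.6f %12.6f %12.6f\n", x$symbols[i],
                if (x$ghost[i]) "*" else " ", ang[i, 1], ang[i, 2], ang[i, 3]))
  invisible(x)
}

n_electrons <- function(mol) sum(mol$Z) - mol$charge

#' Read a molecule from an XYZ file
#'
#' Standard XYZ format: first line the atom count, second line a comment,
#' then one `El x y z` line per atom with coordinates in Angstrom.
#'
#' @param path path to the XYZ file.
#' @param charge total molecular charge.
#' @return an object of class `hipres_mol`.
#' @export
read_xyz <- function(path, charge = 0) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file: ", path)
  toks <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  symbols <- vapply(toks, `[`, "", 1)
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  molecule(symbols, coords, charge = charge)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a `hipres_mol`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "") {
  ang <- mol$xyz / bohr_per_angstrom
  lines <- c(length(mol$symbols), comment,
             sprintf("%-2s %16.10f %16.10f %16.10f", mol$symbols, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

## replace coordinates (bohr) keeping everything else
set_coords_bohr <- function(mol, xyz) {
  mol$xyz <- matrix(xyz, ncol = 3)
  mol
}
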