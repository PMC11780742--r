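## Gaussian basis sets: a small parser for the Gaussian94-style text
## format (S, P, D, F and SP blocks), shell construction per atom, and
## contracted normalization.

.l_of <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)

## parse one basis file into a per-element list of shells
parse_basis_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*!", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    el <- hdr[1]
    i <- i + 1
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      np <- as.integer(sh[2])
      rows <- do.call(rbind, lapply(lines[(i + 1):(i + np)], function(l) {
        as.numeric(gsub("[DdEe]([+-])", "e\\1", strsplit(l, "\\s+")[[1]]))
      }))
      i <- i + np + 1
      if (type == "SP") {
        shells[[length(shells) + 1]] <- list(l = 0L, exp = rows[, 1], coef = rows[, 2])
        shells[[length(shells) + 1]] <- list(l = 1L, exp = rows[, 1], coef = rows[, 3])
      } else {
        l <- .l_of[[type]]
        if (is.null(l)) stop("unsupported shell type: ", type)
        shells[[length(shells) + 1]] <- list(l = l, exp = rows[, 1], coef = rows[, 2])
      }
    }
    out[[el]] <- shells
  }
  out
}

double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

## norm of a primitive Cartesian Gaussian with angular momentum (l,0,0)
primitive_norm <- function(alpha, l) {
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(double_factorial(2 * l - 1))
}

## normalize a contracted shell: fold primitive norms into coefficients,
## then scale so the (l,0,0) component has unit self-overlap
normalize_shell <- function(l, ex, cf) {
  cf <- cf * vapply(ex, primitive_norm, 0, l = l)
  p <- outer(ex, ex, "+")
  s11 <- double_factorial(2 * l - 1) / (2 * p)^l * (pi / p)^1.5
  s <- sum(outer(cf, cf) * s11)
  cf / sqrt(s)
}

#' Load a Gaussian basis set for a molecule
#'
#' Resolves a basis-set name (currently `"sto-3g"`, shipped with the
#' package) or a path to a Gaussian94-format file, and attaches shells to
#' every atom of the molecule.  Ghost atoms receive basis functions like
#' real atoms.  Basis functions are Cartesian Gaussians; components are
#' ordered lexicographically (lx descending, then ly).
#'
#' @param mol a `hipres_mol`.
#' @param basis basis-set name or file path.
#' @return an object of class `hipres_basis`: a list with `shells` (each
#'   with `l`, `center` in bohr, `exp`, `coef`, `atom`), `nbf`, and the
#'   per-basis-function atom map `ao_atom`.
#' @export
load_basis <- function(mol, basis = "sto-3g") {
  path <- if (file.exists(basis)) basis else
    system.file("extdata", "basis", paste0(tolower(basis), ".txt"), package = "hipres")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown basis set: ", basis)
  tab <- parse_basis_file(path)
  shells <- list()
  for (ia in seq_along(mol$symbols)) {
    el <- mol$symbols[ia]
    if (is.null(tab[[el]])) stop("basis ", basis, " has no entry for element ", el)
    for (sh in tab[[el]]) {
      shells[[length(shells) + 1]] <- list(
        l = sh$l, center = mol$xyz[ia, ],
        exp = sh$exp, coef = normalize_shell(sh$l, sh$exp, sh$coef),
        atom = ia)
    }
  }
  nbf_shell <- vapply(shells, function(s) ((s$l + 1L) * (s$l + 2L)) %/% 2L, 0L)
  ao_atom <- rep(vapply(shells, `[[`, 0L, "atom"), nbf_shell)
  structure(list(shells = shells, nbf = sum(nbf_shell), ao_atom = ao_atom,
                 name = basis, mol = mol),
            class = "hipres_basis")
}

#' @export
print.hipres_basis <- function(x, ...) {
  cat(sprintf("<hipres_basis> %s: %d shells, %d Cartesian basis functions\n",
              x$name, length(x$shells), x$nbf))
  invisible(x)
}
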