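## R-level surface of the three-center integral engine.  The same C++
## kernels power the integral-direct contractions inside the SCF; these
## wrappers materialize full blocks for inspection and testing and are
## meant for small inputs only.

tess_fields <- function(tesserae) {
  if (inherits(tesserae, "gost_cavity"))
    return(list(r = tesserae$centers, w = tesserae$omega, N = tesserae$N,
                n = tesserae$normal))
  list(r = matrix(tesserae$centers, ncol = 3),
       w = as.numeric(tesserae$omega),
       N = as.numeric(tesserae$N),
       n = matrix(tesserae$normal, ncol = 3))
}

#' Three-center overlap integrals with tessera Gaussians
#'
#' `g_integrals` returns the overlaps `<mu | G_j | nu>` of all basis-pair
#' products with the normalized s-type tessera Gaussians;
#' `f_integrals` the scalar product of the tessera normal with the
#' gradient of `g` with respect to the tessera center (p-type overlaps).
#' Both are symmetric under exchange of `mu` and `nu`.
#'
#' @param basis a `hipres_basis`.
#' @param tesserae a `gost_cavity` or a list with `centers`, `omega`, `N`,
#'   `normal`.
#' @return array of dimension (nbf, nbf, n_tess).
#' @export
g_integrals <- function(basis, tesserae) {
  t <- tess_fields(tesserae)
  gost_blocks_cpp(basis$shells, t$r, t$w, t$N, t$n, "g")$g
}

#' @rdname g_integrals
#' @export
f_integrals <- function(basis, tesserae) {
  t <- tess_fields(tesserae)
  gost_blocks_cpp(basis$shells, t$r, t$w, t$N, t$n, "f")$f
}

#' Exponent derivatives of the tessera integrals
#'
#' Derivatives of the `g` and `f` integrals with respect to the tessera
#' Gaussian exponent at fixed normalization constant (the
#' normalization-constant derivatives cancel in the full gradient and are
#' excluded).  The `g` derivative is an s x d-type tessera overlap, the
#' `f` derivative a combination of p/f-type overlaps.
#'
#' @inheritParams g_integrals
#' @return list of arrays `dg`, `df` of dimension (nbf, nbf, n_tess).
#' @export
exponent_derivative_integrals <- function(basis, tesserae) {
  t <- tess_fields(tesserae)
  b <- gost_blocks_cpp(basis$shells, t$r, t$w, t$N, t$n, c("gw", "fw"))
  list(dg = b$gw, df = b$fw)
}

#' Center derivatives of the tessera integrals
#'
#' Nuclear-derivative blocks at constant exponents: derivatives of `g` and
#' `f` with respect to the bra shell center, the ket shell center, and the
#' tessera center.  The three blocks sum to zero componentwise
#' (translational invariance), which the gradient code exploits by
#' differentiating only the bra side.
#'
#' @inheritParams g_integrals
#' @return list of arrays `dgdA`, `dgdB`, `dgdC`, `dfdA`, `dfdB`, `dfdC`,
#'   each of dimension (nbf, nbf, n_tess, 3).
#' @export
bra_derivative_integrals <- function(basis, tesserae) {
  t <- tess_fields(tesserae)
  gost_blocks_cpp(basis$shells, t$r, t$w, t$N, t$n,
                  c("dgdA", "dgdB", "dgdC", "dfdA", "dfdB", "dfdC"))
}

#' Conservative screening bounds for tessera-integral batches
#'
#' Upper bounds on `max |g|` and `max |f|` over each (shell pair, tessera)
#' batch, built from pointwise Gaussian envelopes of the contracted shells
#' and the closed-form overlap of three s-Gaussians.  The bounds are
#' provably no smaller than the true maxima, so screening with
#' `bound < threshold` never skips a contributing batch.
#'
#' @inheritParams g_integrals
#' @param threshold screening threshold; batches with bound below it are
#'   marked skippable.
#' @return list with arrays `bound_g`, `bound_f` (nshell x nshell x
#'   n_tess) and logical `skip` of the same shape.
#' @export
screen_batches <- function(basis, tesserae, threshold = 1e-12) {
  t <- tess_fields(tesserae)
  b <- gost_bound_cpp(basis$shells, t$r, t$w, t$N, t$n)
  list(bound_g = b$g, bound_f = b$f, skip = pmax(b$g, b$f) < threshold)
}
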