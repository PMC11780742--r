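## GOSTSHYP working quantities.
##
## The model places on every cavity tessera j a repulsive potential
## p_j * G_j(r) with G_j the normalized Gaussian
## N_j exp(-omega_j |r - r_j|^2).  Per SCF iteration two auxiliary vectors
## are contracted from the density matrix,
##   g~_j = sum_{mu,nu} D_{mu,nu} <mu|G_j|nu>,
##   f~_j = sum_{mu,nu} D_{mu,nu} n_j . grad_{r_j} <mu|G_j|nu>,
## and the semiclassical force balance on each surface element (pressure
## times area equals the force the potential exerts on the density) fixes
## the amplitudes
##   p_j = - p_inp a_j / f~_j.
## The sign convention makes amplitudes positive on a well-formed convex
## surface, where moving the Gaussian outward along the normal decreases
## the density overlap (f~_j < 0); negative amplitudes signal cavity
## artifacts (crevices).  The energy is E_G = sum_j p_j g~_j and the
## Fock-matrix contribution its density derivative,
##   F_{mu,nu} = sum_j p_j [ g_{mu nu j} - (g~_j/f~_j) f_{mu nu j} ].

pressure_to_au <- function(gpa) gpa / gpa_per_au

.ft_floor <- 1e-12

#' Auxiliary vectors of the pressure model
#'
#' Contracts the density matrix with the three-center `g` and `f`
#' integrals, batchwise and integral-direct (no quantity of size
#' nbf^2 x n_tess is formed).  Optionally also returns the
#' exponent-derivative contractions needed by the analytic gradient.
#'
#' @param basis a `hipres_basis`.
#' @param density symmetric density matrix (nbf x nbf).
#' @param cavity a `gost_cavity`.
#' @param threshold screening threshold for (shell pair, tessera) batches.
#' @param exponent_derivatives also contract the exponent-derivative
#'   integrals.
#' @return list with `gt`, `ft` (and `gw`, `fw` if requested), plus
#'   screening counters `skipped`/`total`.
#' @export
compute_aux_vectors <- function(basis, density, cavity, threshold = 1e-12,
                                exponent_derivatives = FALSE) {
  stopifnot(nrow(density) == basis$nbf, ncol(density) == basis$nbf)
  gost_aux_cpp(basis$shells, density, cavity$centers, cavity$omega, cavity$N,
               cavity$normal, threshold, exponent_derivatives)
}

#' Tessera amplitudes from the force balance
#'
#' `p_j = -p_inp a_j / f~_j` in atomic units, with entries regularized to
#' zero where `|f~_j|` falls below the floor `1e-12`.  Negative amplitudes
#' are kept unmodified and counted; they diagnose cavity artifacts.
#'
#' @param pressure input pressure in GPa.
#' @param cavity a `gost_cavity`.
#' @param ft auxiliary vector `f~`.
#' @return list with `p` (hartree bohr^3 amplitudes), `n_negative`, and
#'   `n_regularized`.
#' @export
compute_amplitudes <- function(pressure, cavity, ft) {
  p_au <- pressure_to_au(pressure)
  p <- numeric(cavity$n)
  ok <- abs(ft) >= .ft_floor
  p[ok] <- -p_au * cavity$area[ok] / ft[ok]
  list(p = p, n_negative = sum(p < 0), n_regularized = sum(!ok))
}

#' Pressure energy and effective volume
#'
#' `gostshyp_energy` assembles `E_G = sum_j p_j g~_j`;
#' `effective_volume` is the conjugate ratio `V_eff = E_G / p_inp`
#' (not the geometric cavity volume).
#'
#' @param p amplitude vector.
#' @param gt auxiliary vector `g~`.
#' @return energy in hartree.
#' @export
gostshyp_energy <- function(p, gt) sum(p * gt)

#' @rdname gostshyp_energy
#' @param e_g pressure energy in hartree.
#' @param pressure input pressure in GPa.
#' @return volume in bohr^3.
#' @export
effective_volume <- function(e_g, pressure) {
  if (pressure == 0) stop("effective volume is undefined at zero pressure")
  e_g / pressure_to_au(pressure)
}

#' Fock-matrix contribution of the pressure model
#'
#' Assembles `F = sum_j p_j [g_j - (g~_j/f~_j) f_j]` in a second
#' integral pass, accumulating per-tessera terms on the fly.  The result
#' is the derivative of the pressure energy with respect to the density
#' matrix.
#'
#' @inheritParams compute_aux_vectors
#' @param p amplitude vector.
#' @param gt,ft auxiliary vectors for the same density.
#' @return symmetric matrix (nbf x nbf).
#' @export
fock_contribution <- function(basis, cavity, p, gt, ft, threshold = 1e-12) {
  q <- numeric(cavity$n)
  ok <- p != 0 & abs(ft) >= .ft_floor
  q[ok] <- -p[ok] * gt[ok] / ft[ok]
  gost_fock_cpp(basis$shells, cavity$centers, cavity$omega, cavity$N, cavity$normal,
                p, q, threshold)
}
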