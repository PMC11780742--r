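## Analytic nuclear gradients.
##
## The pressure-energy gradient combines, per tessera j with amplitude
## p_j = -p_inp a_j / f~_j and q_j = -p_j g~_j / f~_j:
##   * the center-derivative part: constant-exponent derivatives of the
##     three-center integrals contracted with the density (bra and ket
##     derivatives coded, tessera-center derivatives from translational
##     invariance), with coefficients p_j on dg and q_j on df;
##   * the exponent part: the exponent-derivative auxiliary contractions
##     routed through d(omega)/dR = -(omega/a) da/dR;
##   * the area part: the explicit a_j dependence of the amplitudes,
##     (p_j g~_j / a_j) da/dR.
## Density-matrix derivatives are not included here; they are carried by
## the host engine's energy-weighted density (which is built from the
## total Fock matrix, pressure term included).

#' Pressure-model contribution to the nuclear gradient
#'
#' Computes the analytic gradient of the GOSTSHYP energy at the converged
#' density, split into a center-derivative (integral) part, an exponent
#' part and an area part that sum to the total.
#'
#' @param scf a converged `hipres_scf` at nonzero pressure.
#' @return list with `total` (n_atom x 3, hartree/bohr) and the
#'   components `integral`, `exponent`, `area`.
#' @export
gost_gradient <- function(scf) {
  natom <- length(scf$mol$symbols)
  zero <- matrix(0, natom, 3)
  if (scf$pressure == 0 || is.null(scf$cavity))
    return(list(total = zero, integral = zero, exponent = zero, area = zero))
  if (!scf$converged) stop("gradient requires a converged SCF state")
  cav <- scf$cavity
  bas <- scf$basis
  aux <- compute_aux_vectors(bas, scf$D, cav, threshold = 0, exponent_derivatives = TRUE)
  gt <- aux$gt; ft <- aux$ft
  ampl <- compute_amplitudes(scf$pressure, cav, ft)
  p <- ampl$p
  q <- numeric(cav$n)
  ok <- p != 0
  q[ok] <- -p[ok] * gt[ok] / ft[ok]
  ## center-derivative (constant-exponent) part
  g_int <- gost_grad_cpp(bas$shells, scf$D, cav$centers, cav$omega, cav$N, cav$normal,
                         p, q, as.integer(cav$parent), natom, 0)
  ## cavity derivative table
  darea <- cavity_derivatives(cav, scf$mol)
  contract_tess <- function(coef) {
    out <- matrix(0, natom, 3)
    for (d in 1:3) out[, d] <- colSums(coef * darea[, , d, drop = FALSE][, , 1])
    out
  }
  g_exp <- contract_tess((p * aux$gw + q * aux$fw) * (-cav$omega / cav$area))
  g_area <- contract_tess(ifelse(ok, p * gt / cav$area, 0))
  list(total = g_int + g_exp + g_area,
       integral = g_int, exponent = g_exp, area = g_area)
}

#' Host Hartree-Fock nuclear gradient
#'
#' Standard closed-shell RHF gradient: core-Hamiltonian and two-electron
#' derivative contractions with the density, the Pulay term with the
#' energy-weighted density (built from the total Fock matrix, so the
#' pressure coupling's density response is included), and nuclear
#' repulsion.
#'
#' @param scf a converged `hipres_scf`.
#' @return matrix (n_atom x 3) in hartree/bohr.
#' @export
hf_gradient <- function(scf) {
  mol <- scf$mol
  one <- hf_grad_onee_cpp(scf$basis$shells, mol$xyz, as.numeric(mol$Z), scf$D, scf$W)
  two <- hf_grad_eri_cpp(scf$basis$shells, scf$D, length(mol$symbols))
  one$hcore + two - one$overlap + nuclear_repulsion_gradient(mol)
}

#' Total nuclear gradient under pressure
#'
#' Host gradient plus the pressure-model block.
#'
#' @param scf a converged `hipres_scf`.
#' @return matrix (n_atom x 3) in hartree/bohr.
#' @export
total_gradient <- function(scf) {
  hf_gradient(scf) + gost_gradient(scf)$total
}

#' Geometry optimization under pressure
#'
#' Drives a quasi-Newton (BFGS) optimizer with the total analytic
#' gradient.  Convergence is declared when the energy change between
#' accepted steps falls below `conv_energy` and the gradient norm below
#' `conv_gnorm`.  Only smooth cavities (`vdw`, `vdw_occ`) are supported.
#'
#' @param mol starting geometry.
#' @param basis,pressure,cavity,r_ext,grid_points,radii,screen_thresh
#'   forwarded to [run_scf()].
#' @param conv_energy energy-change threshold (hartree).
#' @param conv_gnorm gradient-norm threshold (hartree/Angstrom).
#' @param max_steps maximum geometry steps.
#' @return list with the optimized `mol`, final `energy`, per-step
#'   energies `trajectory`, `gnorm` and `converged`.
#' @export
optimize_geometry <- function(mol, basis = "sto-3g", pressure = 0, cavity = "vdw_occ",
                              r_ext = 0.25, grid_points = 110, radii = NULL,
                              screen_thresh = 1e-12,
                              conv_energy = 1e-6, conv_gnorm = 1e-3, max_steps = 60) {
  if (is.character(cavity) && !(cavity[1] %in% c("vdw", "vdw_occ", "none")))
    stop("geometry optimization supports only the smooth 'vdw'/'vdw_occ' cavities")
  traj <- new.env(parent = emptyenv())
  traj$E <- numeric(0)
  traj$X <- list()
  scf_at <- function(x) {
    m <- set_coords_bohr(mol, x)
    run_scf(m, basis = basis, pressure = pressure, cavity = cavity, r_ext = r_ext,
            grid_points = grid_points, radii = radii, conv_energy = 1e-10,
            conv_orb = 1e-7, screen_thresh = screen_thresh, max_iter = 200)
  }
  fn <- function(x) {
    s <- scf_at(x)
    traj$E <- c(traj$E, s$energy)
    traj$X[[length(traj$X) + 1]] <- matrix(x, ncol = 3)
    s$energy
  }
  gr <- function(x) as.vector(total_gradient(scf_at(x)))
  x0 <- as.vector(mol$xyz)
  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = max_steps, reltol = 1e-12))
  s <- scf_at(opt$par)
  g <- total_gradient(s)
  gnorm <- sqrt(sum(g^2)) * bohr_per_angstrom  # hartree/Angstrom
  list(mol = set_coords_bohr(mol, opt$par), energy = s$energy,
       trajectory = traj$E, geometries = traj$X, gnorm = gnorm,
       converged = gnorm <= conv_gnorm, scf = s)
}
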