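## Restricted Hartree-Fock driver with the GOSTSHYP pressure coupling.
##
## The cavity is built once before the iterations; every SCF cycle then
## performs two integral-direct passes over the tessera integrals: pass 1
## contracts the current density into the auxiliary vectors (from which
## amplitudes and the pressure energy follow at no extra cost), pass 2
## accumulates the Fock-matrix contribution.  Convergence is accelerated
## by DIIS extrapolation of the total Fock matrix (host + pressure term).

nuclear_repulsion <- function(mol) {
  e <- 0
  n <- length(mol$Z)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (mol$Z[i] == 0 || mol$Z[j] == 0) next
    e <- e + mol$Z[i] * mol$Z[j] / sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2))
  }
  e
}

nuclear_repulsion_gradient <- function(mol) {
  n <- length(mol$Z)
  g <- matrix(0, n, 3)
  if (n < 2) return(g)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (mol$Z[i] == 0 || mol$Z[j] == 0) next
    d <- mol$xyz[i, ] - mol$xyz[j, ]
    r <- sqrt(sum(d^2))
    f <- -mol$Z[i] * mol$Z[j] / r^3 * d
    g[i, ] <- g[i, ] + f
    g[j, ] <- g[j, ] - f
  }
  g
}

.cavity_types <- c("vdw", "vdw_occ", "none")

resolve_cavity <- function(mol, cavity, radii, grid_points, r_ext) {
  if (inherits(cavity, "gost_cavity")) return(cavity)
  cavity <- as.character(cavity)[1]
  if (cavity %in% c("ses", "isodensity", "fine"))
    stop("cavity type '", cavity, "' is not supported; use 'vdw' or 'vdw_occ'")
  cavity <- match.arg(cavity, .cavity_types)
  if (cavity == "none") return(NULL)
  build_vdw_cavity(mol, radii = radii, grid_points = grid_points,
                   r_ext = if (cavity == "vdw_occ") r_ext else 0)
}

#' Self-consistent field calculation under hydrostatic pressure
#'
#' Runs a restricted Hartree-Fock calculation with the GOSTSHYP pressure
#' coupling.  At `pressure = 0` the pressure term is exactly absent and
#' the gas-phase energy is recovered.
#'
#' @param mol a `hipres_mol` (closed-shell electron count).
#' @param basis basis-set name or file (see [load_basis()]).
#' @param pressure input pressure in GPa.
#' @param cavity `"vdw"`, `"vdw_occ"`, `"none"`, or a prebuilt
#'   `gost_cavity`.
#' @param r_ext outer-cavity-correction extension radius in Angstrom
#'   (used with `cavity = "vdw_occ"`).
#' @param grid_points Lebedev points per atom.
#' @param radii named per-element cavity radii in Angstrom (default
#'   Bondi).
#' @param conv_energy SCF energy convergence threshold (hartree).
#' @param conv_orb convergence threshold on the maximum DIIS error.
#' @param max_iter maximum number of SCF cycles.
#' @param screen_thresh tessera-integral screening threshold (0 disables).
#' @param D0 optional starting density matrix.
#' @param verbose print one line per iteration.
#' @return object of class `hipres_scf` with the total `energy`
#'   (hartree), pressure energy `e_gost`, effective volume `v_eff`
#'   (bohr^3, `NA` at zero pressure), amplitude vector `amplitudes`,
#'   `n_negative`, iteration count `niter`, `converged`, and the matrices
#'   needed by the gradient code.
#' @export
run_scf <- function(mol, basis = "sto-3g", pressure = 0, cavity = "vdw",
                    r_ext = 0.25, grid_points = 110, radii = NULL,
                    conv_energy = 1e-7, conv_orb = 1e-6, max_iter = 128,
                    screen_thresh = 1e-12, D0 = NULL, verbose = FALSE) {
  if (pressure < 0) stop("pressure must be >= 0")
  bas <- load_basis(mol, basis)
  n <- bas$nbf
  nel <- n_electrons(mol)
  if (nel %% 2 != 0) stop("only closed-shell systems are supported (even electron count)")
  nocc <- nel %/% 2
  if (nocc > n) stop("more electron pairs than basis functions")

  ints <- one_electron_cpp(bas$shells, mol$xyz, as.numeric(mol$Z))
  S <- ints$S; H <- ints$T + ints$V
  enuc <- nuclear_repulsion(mol)

  eri <- eri_cpp(bas$shells, 1e-14)
  JM <- matrix(eri, n * n, n * n)
  KM <- matrix(aperm(array(eri, c(n, n, n, n)), c(1, 3, 2, 4)), n * n, n * n)
  rm(eri)

  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("near-singular overlap matrix")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)

  cav <- if (pressure > 0) resolve_cavity(mol, cavity, radii, grid_points, r_ext) else NULL
  if (pressure > 0 && is.null(cav))
    stop("a cavity is required at nonzero pressure")

  make_density <- function(F) {
    Ft <- t(X) %*% F %*% X
    e <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(e$values)  # ascending orbital energies
    C <- X %*% e$vectors[, ord, drop = FALSE]
    list(D = 2 * C[, 1:nocc, drop = FALSE] %*% t(C[, 1:nocc, drop = FALSE]),
         C = C, eps = e$values[ord])
  }

  if (is.null(D0)) {
    guess <- make_density(H)
    D <- guess$D
  } else D <- D0

  diis_F <- list(); diis_E <- list()
  e_old <- Inf; conv <- FALSE
  Eg <- 0; veff <- NA_real_; amp <- numeric(0); n_neg <- 0L; neg_hist <- integer(0)
  gt <- ft <- NULL; orb <- NULL
  for (iter in seq_len(max_iter)) {
    J <- matrix(JM %*% as.vector(D), n, n)
    K <- matrix(KM %*% as.vector(D), n, n)
    G <- J - 0.5 * K
    Fg <- 0
    if (pressure > 0) {
      aux <- compute_aux_vectors(bas, D, cav, screen_thresh)
      gt <- aux$gt; ft <- aux$ft
      ampl <- compute_amplitudes(pressure, cav, ft)
      amp <- ampl$p; n_neg <- ampl$n_negative
      neg_hist <- c(neg_hist, n_neg)
      Eg <- gostshyp_energy(amp, gt)
      Fg <- fock_contribution(bas, cav, amp, gt, ft, screen_thresh)
    }
    F <- H + G + Fg
    E <- sum(D * H) + 0.5 * sum(D * G) + Eg + enuc
    err <- F %*% D %*% S - S %*% D %*% F
    err <- t(X) %*% err %*% X
    maxerr <- max(abs(err))
    if (verbose)
      message(sprintf("iter %3d  E = %18.10f  dE = %10.3e  err = %8.2e  n(p<0) = %d",
                      iter, E, E - e_old, maxerr, n_neg))
    if (abs(E - e_old) < conv_energy && maxerr < conv_orb) {
      conv <- TRUE
      orb <- make_density(F)
      e_old <- E
      break
    }
    e_old <- E
    ## DIIS extrapolation
    diis_F[[length(diis_F) + 1]] <- F
    diis_E[[length(diis_E) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_E <- diis_E[-1] }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m) B[i, j] <- sum(diis_E[[i]] * diis_E[[j]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    orb <- make_density(F)
    D <- orb$D
  }
  if (pressure > 0 && Eg != 0) veff <- effective_volume(Eg, pressure)
  eps <- orb$eps; C <- orb$C
  W <- 2 * C[, 1:nocc, drop = FALSE] %*% diag(eps[1:nocc], nocc) %*%
    t(C[, 1:nocc, drop = FALSE])
  structure(list(
    energy = e_old, e_gost = Eg, e_nuc = enuc,
    v_eff = veff, amplitudes = amp, n_negative = n_neg,
    neg_history = neg_hist, gt = gt, ft = ft,
    niter = iter, converged = conv,
    D = D, C = C, eps = eps, W = W, S = S,
    basis = bas, mol = mol, cavity = cav, pressure = pressure,
    screen_thresh = screen_thresh, nocc = nocc
  ), class = "hipres_scf")
}

#' @export
print.hipres_scf <- function(x, ...) {
  cat(sprintf("<hipres_scf> E = %.10f hartree (%s in %d cycles)\n",
              x$energy, if (x$converged) "converged" else "NOT converged", x$niter))
  if (x$pressure > 0)
    cat(sprintf("  p = %g GPa: E_G = %.8f hartree, V_eff = %.4f bohr^3, %d negative amplitude(s) on %d tesserae\n",
                x$pressure, x$e_gost, x$v_eff, x$n_negative, x$cavity$n))
  invisible(x)
}
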