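# The restricted Hartree-Fock engine and its pressure coupling.

test_that("minimal-basis H2 reproduces the closed-form symmetric RHF energy", {
  fx <- make_fixture("h2")
  s <- run_scf(fx$mol, pressure = 0)
  expect_true(s$converged)
  # independent route: with two equivalent s AOs the occupied MO is fixed
  # by symmetry, phi = (chi1 + chi2)/sqrt(2(1+S12)), and
  # E = 2 h_phi + (phi phi|phi phi) + E_nn needs no SCF at all
  bas <- load_basis(fx$mol)
  ints <- ns$one_electron_cpp(bas$shells, fx$mol$xyz, as.numeric(fx$mol$Z))
  H <- ints$T + ints$V
  eri <- array(ns$eri_cpp(bas$shells, 0), c(2, 2, 2, 2))
  cvec <- c(1, 1) / sqrt(2 * (1 + ints$S[1, 2]))
  dd <- cvec %o% cvec
  e_cf <- 2 * sum(dd * H) + sum(outer(dd, dd) * eri) + ns$nuclear_repulsion(fx$mol)
  expect_equal(s$energy, e_cf, tolerance = 1e-12)
})

test_that("fixture energies agree with textbook minimal-basis values", {
  expect_equal(run_scf(make_fixture("h2o")$mol)$energy, -74.9629, tolerance = 2e-4)
  expect_equal(run_scf(make_fixture("ch4")$mol)$energy, -39.7269, tolerance = 2e-4)
})

test_that("zero pressure leaves the gas phase exactly and all amplitudes vanish", {
  fx <- make_fixture("h2o")
  cav <- build_vdw_cavity(fx$mol, grid_points = 50)
  am <- compute_amplitudes(0, cav, rep(-1e-3, cav$n))
  expect_true(all(am$p == 0))
  expect_identical(am$n_negative, 0L)
  expect_equal(gostshyp_energy(am$p, rep(1, cav$n)), 0)
  Fg <- fock_contribution(load_basis(fx$mol), cav, am$p, rep(1, cav$n),
                          rep(-1e-3, cav$n))
  expect_equal(max(abs(Fg)), 0)
  expect_error(effective_volume(0, 0), "undefined")
})

test_that("auxiliary vectors are linear in the density and nonnegative for valid densities", {
  fx <- make_fixture("h2")
  s <- tight_scf(fx$mol, pressure = 0)
  cav <- build_vdw_cavity(fx$mol, grid_points = 50)
  bas <- s$basis
  a1 <- compute_aux_vectors(bas, s$D, cav, 0)
  a2 <- compute_aux_vectors(bas, 2 * s$D, cav, 0)
  expect_equal(a2$gt, 2 * a1$gt, tolerance = 1e-13)
  expect_equal(a2$ft, 2 * a1$ft, tolerance = 1e-13)
  a0 <- compute_aux_vectors(bas, 0 * s$D, cav, 0)
  expect_true(all(a0$gt == 0) && all(a0$ft == 0))
  # g~ is a density contracted with a nonnegative weight
  expect_true(all(a1$gt >= 0))
  # single-tessera check against density quadrature: g~_j = int rho G_j,
  # summed over the full primitive contraction of both H shells
  j <- which.max(a1$gt)
  rho_g <- 0
  for (p1 in 1:2) for (p2 in 1:2) {
    s1 <- bas$shells[[p1]]; s2 <- bas$shells[[p2]]
    for (k1 in seq_along(s1$exp)) for (k2 in seq_along(s2$exp))
      rho_g <- rho_g + s$D[p1, p2] * s1$coef[k1] * s2$coef[k2] * cav$N[j] *
        quadrature_oracle(rbind(s1$center, s2$center, cav$centers[j, ]),
                          c(s1$exp[k1], s2$exp[k2], cav$omega[j]),
                          matrix(0, 3, 3))
  }
  expect_equal(a1$gt[j], rho_g, tolerance = 1e-9)
})

test_that("amplitudes scale homogeneously with the input pressure", {
  fx <- make_fixture("h2o")
  s <- run_scf(fx$mol, pressure = 10, cavity = "vdw_occ")
  am1 <- compute_amplitudes(10, s$cavity, s$ft)
  am2 <- compute_amplitudes(20, s$cavity, s$ft)
  expect_equal(am2$p, 2 * am1$p, tolerance = 1e-14)
  # near-singular f~ entries are regularized to zero, not Inf
  ft <- s$ft; ft[1] <- 1e-15
  amr <- compute_amplitudes(10, s$cavity, ft)
  expect_identical(amr$p[1], 0)
  expect_identical(amr$n_regularized, 1L)
})

test_that("the energy sum and effective volume follow their definitions", {
  expect_equal(gostshyp_energy(2, 0.5), 1.0)
  expect_equal(gostshyp_energy(c(1, 2), c(0.25, 0.5)), 1.25)
  # V_eff = E_G / p_inp on the atomic-unit pressure scale
  expect_equal(effective_volume(1, 29421.0265), 1, tolerance = 1e-10)
})

test_that("the Fock term is the density derivative of the pressure energy", {
  fx <- make_fixture("h2o")
  s <- tight_scf(fx$mol, pressure = 10, cavity = "vdw_occ", grid_points = 50)
  bas <- s$basis; cav <- s$cavity
  eg_of <- function(D) {
    aux <- compute_aux_vectors(bas, D, cav, 0)
    gostshyp_energy(compute_amplitudes(10, cav, aux$ft)$p, aux$gt)
  }
  aux <- compute_aux_vectors(bas, s$D, cav, 0)
  am <- compute_amplitudes(10, cav, aux$ft)
  Fg <- fock_contribution(bas, cav, am$p, aux$gt, aux$ft, 0)
  expect_lt(max(abs(Fg - t(Fg))), 1e-14)
  set.seed(11)
  for (k in 1:5) {
    dd <- matrix(rnorm(bas$nbf^2), bas$nbf); dd <- dd + t(dd)
    eps <- 1e-6
    fd <- (eg_of(s$D + eps * dd) - eg_of(s$D - eps * dd)) / (2 * eps)
    expect_equal(sum(Fg * dd), fd, tolerance = 1e-7)
  }
})

test_that("energy rises monotonically with pressure and V_eff shrinks", {
  fx <- make_fixture("h2o")
  runs <- lapply(c(0, 1, 5, 10, 20), function(p)
    run_scf(fx$mol, pressure = p, cavity = "vdw_occ"))
  e <- vapply(runs, `[[`, 0, "energy")
  expect_true(all(diff(e) > 0))
  v <- vapply(runs[-1], `[[`, 0, "v_eff")
  expect_true(all(diff(v) < 0))
  expect_true(all(vapply(runs, `[[`, TRUE, "converged")))
})

test_that("restarting from the converged density reconverges immediately", {
  fx <- make_fixture("h2")
  s <- run_scf(fx$mol, pressure = 10, cavity = "vdw_occ")
  s2 <- run_scf(fx$mol, pressure = 10, cavity = "vdw_occ", D0 = s$D)
  expect_lte(s2$niter, 2)
  expect_equal(s2$energy, s$energy, tolerance = 1e-8)
})

test_that("intermediate pressure quantities stay O(nbf^2 + n_tess) in memory", {
  fx <- make_fixture("h2o")
  bas <- load_basis(fx$mol)
  D <- diag(bas$nbf)
  sizes <- vapply(c(26, 110), function(gp) {
    cav <- build_vdw_cavity(fx$mol, grid_points = gp)
    aux <- compute_aux_vectors(bas, D, cav, 1e-12)
    as.numeric(object.size(aux))
  }, 0)
  # returned state grows linearly with the tessera count and never holds a
  # 3-index (nbf^2 x n_tess) block
  cav_big <- build_vdw_cavity(fx$mol, grid_points = 110)
  expect_lt(sizes[2], 8 * bas$nbf^2 * cav_big$n)
  expect_lt(sizes[2] / sizes[1], 10)
})
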