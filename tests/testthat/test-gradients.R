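# Analytic nuclear gradients: the Hartree-Fock host part and the pressure
# block, against central finite differences of the total energy.  The
# full H2O/CH4 sweep at 10 GPa lives in test-acceptance.R.

test_that("the gas-phase Hartree-Fock gradient matches finite differences", {
  fx <- make_fixture("h2o")
  s <- tight_scf(fx$mol, pressure = 0)
  g <- hf_gradient(s)
  h <- 1e-3
  for (I in c(1, 2)) for (d in c(1, 3)) {
    mp <- fx$mol; mp$xyz[I, d] <- mp$xyz[I, d] + h
    mm <- fx$mol; mm$xyz[I, d] <- mm$xyz[I, d] - h
    fd <- (tight_scf(mp, pressure = 0)$energy - tight_scf(mm, pressure = 0)$energy) / (2 * h)
    expect_equal(g[I, d], fd, tolerance = 1e-5)
  }
})

test_that("the pressure block vanishes at zero pressure and is linear as p -> 0+", {
  fx <- make_fixture("h2")
  s0 <- run_scf(fx$mol, pressure = 0)
  g0 <- gost_gradient(s0)
  expect_equal(max(abs(g0$total)), 0)
  s1 <- tight_scf(fx$mol, pressure = 0.01, cavity = "vdw_occ", grid_points = 50)
  s2 <- tight_scf(fx$mol, pressure = 0.02, cavity = "vdw_occ", grid_points = 50)
  g1 <- gost_gradient(s1)$total
  g2 <- gost_gradient(s2)$total
  expect_equal(g2, 2 * g1, tolerance = 1e-4)
})

test_that("pressure-block components sum to the total and the block is translation-free", {
  fx <- make_fixture("h2o")
  s <- tight_scf(fx$mol, pressure = 10, cavity = "vdw", grid_points = 50)
  gg <- gost_gradient(s)
  expect_equal(gg$total, gg$integral + gg$exponent + gg$area, tolerance = 1e-15)
  expect_lt(max(abs(colSums(gg$total))), 1e-12)
})

test_that("auxiliary-vector gradients match finite differences with the cavity rebuilt", {
  fx <- make_fixture("h2")
  s <- tight_scf(fx$mol, pressure = 20, cavity = "vdw_occ", grid_points = 50)
  # total dE_G/dR via the assembled block against FD of E_G[D fixed]
  # with cavity rebuilt at displaced geometries
  gg <- gost_gradient(s)$total
  eg_at <- function(mol) {
    cav <- build_vdw_cavity(mol, grid_points = 50, r_ext = 0.25)
    bas <- load_basis(mol)
    aux <- compute_aux_vectors(bas, s$D, cav, 0)
    gostshyp_energy(compute_amplitudes(20, cav, aux$ft)$p, aux$gt)
  }
  h <- 1e-5
  for (I in 1:2) for (d in 1:3) {
    mp <- fx$mol; mp$xyz[I, d] <- mp$xyz[I, d] + h
    mm <- fx$mol; mm$xyz[I, d] <- mm$xyz[I, d] - h
    fd <- (eg_at(mp) - eg_at(mm)) / (2 * h)
    expect_equal(gg[I, d], fd, tolerance = 1e-6)
  }
})

test_that("H2 compresses under pressure and the gas-phase optimum is recovered at p = 0", {
  fx <- make_fixture("h2")
  o0 <- optimize_geometry(fx$mol, pressure = 0, cavity = "none")
  oc <- optimize_geometry(fx$mol, pressure = 0, cavity = "vdw_occ", grid_points = 50)
  expect_lt(abs(bond_length_ang(o0$mol) - bond_length_ang(oc$mol)), 1e-4)
  o50 <- optimize_geometry(fx$mol, pressure = 50, cavity = "vdw_occ", grid_points = 50)
  expect_true(o50$converged)
  expect_lt(bond_length_ang(o50$mol), bond_length_ang(o0$mol))
  expect_gt(o50$energy, o0$energy)
})

test_that("gradients refuse unconverged states and unsupported cavities", {
  fx <- make_fixture("h2")
  s <- run_scf(fx$mol, pressure = 10, cavity = "vdw_occ", max_iter = 1)
  expect_false(s$converged)
  expect_error(gost_gradient(s), "converged")
  expect_error(optimize_geometry(fx$mol, cavity = "ses"), "vdw")
})
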