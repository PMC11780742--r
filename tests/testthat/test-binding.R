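# Counterpoise binding energies and the pressure-slope extraction.

test_that("the slope estimator is exact on linear data and flags curvature", {
  st <- structure(data.frame(pressure = 0:5, e_b = 10 + 3.7 * (0:5)),
                  class = c("hipres_binding_study", "data.frame"))
  sl <- pressure_slope(st)
  expect_equal(sl$slope, 3.7, tolerance = 1e-12)
  expect_false(sl$nonlinear)
  st2 <- st; st2$e_b <- 10 + 3.7 * st2$pressure + 0.8 * st2$pressure^2
  expect_true(pressure_slope(st2)$nonlinear)
  expect_error(pressure_slope(st[1:2, ]), ">= 3")
})

test_that("the slope estimator is unbiased on noisy linear data", {
  set.seed(1234)
  p <- 0:5
  hits <- vapply(1:100, function(k) {
    st <- structure(data.frame(pressure = p, e_b = 2 + 1.5 * p + rnorm(6, sd = 0.3)),
                    class = c("hipres_binding_study", "data.frame"))
    sl <- pressure_slope(st)
    abs(sl$slope - 1.5) <= 2 * sl$se_slope
  }, TRUE)
  expect_gt(mean(hits), 0.85)  # ~95% nominal coverage
})

test_that("counterpoise energies vanish for non-interacting fragments", {
  far <- molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(0, 0, 12)))
  cp <- counterpoise_binding_energy(far, list(1, 2), pressure = 0)
  expect_lt(abs(cp$e_b), 1e-5)  # kJ/mol, SCF convergence noise
  raw <- counterpoise_binding_energy(far, list(1, 2), pressure = 0,
                                     counterpoise = FALSE)
  expect_lt(abs(cp$e_b - raw$e_b), 1e-5)
})

test_that("fragment bookkeeping is validated and ghosts carry no charge or cavity", {
  fx <- make_fixture("ne2")
  expect_error(counterpoise_binding_energy(fx$mol, list(1, 1)), "overlap")
  expect_error(counterpoise_binding_energy(fx$mol, list(1, 2:3)), "partition")
  gm <- ns$fragment_mol(fx$mol, 1, 2)
  expect_equal(gm$Z, c(10, 0))
  cav <- build_vdw_cavity(gm, grid_points = 50)
  expect_true(all(cav$parent == 1))
})

test_that("pressure stabilizes the compressed neon dimer", {
  fx <- make_fixture("ne2")
  e0 <- counterpoise_binding_energy(fx$mol, list(1, 2), pressure = 0,
                                    cavity = "vdw_occ", grid_points = 50)$e_b
  e5 <- counterpoise_binding_energy(fx$mol, list(1, 2), pressure = 5,
                                    cavity = "vdw_occ", grid_points = 50)$e_b
  expect_gt(e5, e0)
})
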