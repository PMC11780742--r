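# The test-suite oracles themselves: closed-form checks.

test_that("the quadrature oracle reproduces closed-form Gaussian integrals", {
  expect_equal(quadrature_oracle(matrix(0, 1, 3), 1, matrix(0, 1, 3)), pi^1.5,
               tolerance = 1e-12)
  # shifted and scaled: int exp(-a|r-A|^2) = (pi/a)^{3/2} independent of A
  expect_equal(quadrature_oracle(matrix(c(1, -2, 3), 1), 0.37, matrix(0, 1, 3)),
               (pi / 0.37)^1.5, tolerance = 1e-12)
  # first moment of an offset product of two Gaussians
  a <- 0.9; b <- 1.4
  A <- c(0, 0, 0); B <- c(0, 0, 1)
  # exact: product Gaussian at P = b/(a+b) along z, <(z-Az)^1> = Pz * S
  S <- (pi / (a + b))^1.5 * exp(-a * b / (a + b))
  expect_equal(quadrature_oracle(rbind(A, B), c(a, b), rbind(c(0, 0, 1), c(0, 0, 0))),
               b / (a + b) * S, tolerance = 1e-12)
})

test_that("the finite-difference oracle recovers simple derivatives", {
  fd <- finite_difference_oracle(function(x) x[1]^2, 3, step = 1e-4)
  expect_equal(fd$grad, 6, tolerance = 1e-7)
  # gradient of a quadratic form is exact for central differences
  set.seed(5)
  M <- crossprod(matrix(rnorm(9), 3))
  x0 <- rnorm(3)
  fd2 <- finite_difference_oracle(function(x) 0.5 * sum(x * (M %*% x)), x0,
                                  step = 1e-3, check = TRUE)
  expect_true(fd2$reliable)
  expect_equal(fd2$grad, as.vector(M %*% x0), tolerance = 1e-9)
})

test_that("fixtures are deterministic and well-formed", {
  expect_setequal(fixture_names(),
                  c("h2", "h2o", "ch4", "ne2", "benzene_dimer_crevice"))
  h2 <- make_fixture("h2")
  expect_equal(bond_length_ang(h2$mol), 0.74, tolerance = 1e-12)
  ne2 <- make_fixture("ne2")
  expect_equal(bond_length_ang(ne2$mol), 3.1, tolerance = 1e-12)
  bz <- make_fixture("benzene_dimer_crevice")
  expect_identical(length(bz$mol$symbols), 24L)
  # closest inter-ring carbon contact is the designed 3.2 Angstrom
  dmat <- as.matrix(dist(bz$mol$xyz / ang2bohr))
  expect_equal(min(dmat[1:6, 13:18]), 3.2, tolerance = 1e-6)
  expect_error(make_fixture("nope"), "unknown fixture")
  # every fixture parses, has radii for its elements, and a cavity builds
  for (nm in fixture_names()) {
    fx <- make_fixture(nm)
    radii <- if (is.null(fx$radii)) default_vdw_radii(unique(fx$mol$symbols)) else fx$radii
    expect_true(all(fx$mol$symbols %in% names(radii)))
  }
})
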