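test_that("an isolated atomic sphere is tessellated exactly", {
  m <- molecule("He", matrix(0, 1, 3))
  r_bohr <- 2.0
  cav <- build_vdw_cavity(m, radii = c(He = r_bohr / ang2bohr), grid_points = 110)
  expect_equal(cav$n, 110)
  expect_lt(abs(sum(cav$area) - 4 * pi * r_bohr^2) / (4 * pi * r_bohr^2), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(cav$normal^2)) - 1)), 1e-12)
  # centers on the sphere
  expect_lt(max(abs(sqrt(rowSums(cav$centers^2)) - r_bohr)), 1e-12)
})

test_that("tessera Gaussians satisfy the edge-halving and normalization contracts", {
  fx <- make_fixture("h2o")
  cav <- build_vdw_cavity(fx$mol, grid_points = 50)
  # G(sqrt(a/pi)) = G(0)/2
  ghalf <- exp(-cav$omega * cav$area / pi)
  expect_lt(max(abs(ghalf - 0.5)), 1e-12)
  # integral of N exp(-w r^2) over space = 1, by independent quadrature
  idx <- c(1, ceiling(cav$n / 2), cav$n)
  for (j in idx) {
    v <- quadrature_oracle(matrix(cav$centers[j, ], 1), cav$omega[j],
                           matrix(0, 1, 3), coef = cav$N[j])
    expect_lt(abs(v - 1), 1e-8)
  }
})

test_that("distant atoms give the union of isolated-atom cavities", {
  m <- molecule(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 9)))
  cav <- build_vdw_cavity(m, radii = c(He = 1.4), grid_points = 110)
  r <- 1.4 * ang2bohr
  expect_equal(cav$n, 220)
  expect_equal(sum(cav$area), 2 * 4 * pi * r^2, tolerance = 1e-12)
})

test_that("overlapping spheres reproduce the analytic union surface area", {
  r <- 1.4 * ang2bohr
  sep <- 1.5 * r
  m <- molecule(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, sep / ang2bohr)))
  cav <- build_vdw_cavity(m, radii = c(He = 1.4), grid_points = 194)
  # each sphere loses the cap beyond the midplane: A_cap = 2 pi r (r - sep/2)
  exact <- 2 * (4 * pi * r^2 - 2 * pi * r * (r - sep / 2))
  expect_lt(sum(cav$area), 2 * 4 * pi * r^2)
  expect_lt(abs(sum(cav$area) - exact) / exact, 2e-3)  # switching smoothing
})

test_that("outer-cavity correction reduces the tessera count monotonically", {
  fx <- make_fixture("benzene_dimer_crevice")
  c0 <- build_vdw_cavity(fx$mol, radii = fx$radii, grid_points = 50)
  c1 <- apply_occ(c0, 0.25)
  c2 <- apply_occ(c0, 0.5)
  expect_lte(c1$n, c0$n)
  expect_lte(c2$n, c1$n)
  # r_ext = 0 degenerates to the plain construction
  c3 <- apply_occ(c0, 0)
  expect_equal(c3$centers, c0$centers)
  expect_equal(c3$area, c0$area)
  # an isolated atom is unaffected by any extension
  m <- molecule("Ne", matrix(0, 1, 3))
  expect_equal(build_vdw_cavity(m, grid_points = 110, r_ext = 0.5)$area,
               build_vdw_cavity(m, grid_points = 110)$area)
})

test_that("cavity derivatives match finite differences (vdW and OCC)", {
  fx <- make_fixture("h2o")
  h <- 1e-5
  for (rx in c(0, 0.25)) {
    cav <- build_vdw_cavity(fx$mol, grid_points = 50, r_ext = rx)
    da <- cavity_derivatives(cav)
    for (I in 1:3) for (d in 1:3) {
      mp <- fx$mol; mp$xyz[I, d] <- mp$xyz[I, d] + h
      mm <- fx$mol; mm$xyz[I, d] <- mm$xyz[I, d] - h
      cp <- build_vdw_cavity(mp, grid_points = 50, r_ext = rx)
      cm <- build_vdw_cavity(mm, grid_points = 50, r_ext = rx)
      expect_equal(cp$n, cav$n)
      fd <- (cp$area - cm$area) / (2 * h)
      expect_lt(max(abs(fd - da[, I, d]) / pmax(abs(fd), 1)), 1e-6)
    }
    # rigid-translation consistency of the table
    expect_lt(max(abs(apply(da, c(1, 3), sum))), 1e-12)
  }
  # isolated atom: all area derivatives vanish
  m <- molecule("Ne", matrix(0, 1, 3))
  expect_equal(max(abs(cavity_derivatives(build_vdw_cavity(m, grid_points = 50)))), 0)
})

test_that("the discretized surface responds smoothly to small displacements", {
  fx <- make_fixture("h2o")
  cav <- build_vdw_cavity(fx$mol, grid_points = 50)
  mp <- fx$mol
  mp$xyz[2, 3] <- mp$xyz[2, 3] + 1e-3
  cavp <- build_vdw_cavity(mp, grid_points = 50)
  expect_equal(cavp$n, cav$n)
  expect_lt(max(abs(cavp$area - cav$area)), 0.05)  # O(1e-3) * O(d a/d R)
})

test_that("a cavity dumps to a readable plain-text table", {
  fx <- make_fixture("h2")
  cav <- build_vdw_cavity(fx$mol, grid_points = 26)
  path <- tempfile(fileext = ".txt")
  cavity_dump(cav, path)
  tab <- utils::read.table(path, header = TRUE)
  expect_identical(nrow(tab), cav$n)
  expect_equal(tab$area, cav$area, tolerance = 1e-9)
  expect_setequal(unique(tab$parent), c(1, 2))
})

test_that("configuration errors are reported", {
  m <- molecule("H", matrix(0, 1, 3))
  expect_error(build_vdw_cavity(m, radii = c(C = 1.7)), "radius")
  expect_error(build_vdw_cavity(m, grid_points = 111), "Lebedev")
  expect_error(build_vdw_cavity(m, r_ext = -0.1), "r_ext")
  m2 <- molecule("He", matrix(0, 1, 3))
  expect_error(run_scf(m2, pressure = 1, cavity = "ses"), "not supported")
  expect_error(run_scf(m2, pressure = 1, cavity = "fine"), "not supported")
})

test_that("lebedev grids integrate low-order polynomials exactly", {
  for (n in c(6, 26, 50, 110, 194)) {
    g <- lebedev_grid(n)
    expect_equal(sum(g$weights), 1, tolerance = 1e-13)
    # exact spherical average <x^2> = 1/3 (degree 2, held by every grid)
    expect_equal(sum(g$weights * g$points[, 1]^2), 1 / 3, tolerance = 1e-12)
    if (n >= 26) {
      # degree-4 moments: <x^4> = 1/5, <x^2 y^2> = 1/15
      expect_equal(sum(g$weights * g$points[, 3]^4), 1 / 5, tolerance = 1e-12)
      expect_equal(sum(g$weights * g$points[, 1]^2 * g$points[, 2]^2), 1 / 15,
                   tolerance = 1e-12)
    }
  }
})
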