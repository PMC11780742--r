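# The three-center integral engine against the independent Gauss-Hermite
# quadrature oracle, plus its symmetry, decay, invariance and screening
# contracts.  The exhaustive randomized sweep per angular-momentum class
# lives in test-acceptance.R; here a smaller deterministic sample guards
# each code path.

test_that("g integrals match the concentric closed form", {
  # two s-primitives and the tessera Gaussian at one center:
  # N (pi / (alpha + beta + omega))^{3/2}
  a <- 0.7; b <- 1.3; w <- 2.1; N <- (w / pi)^1.5
  sh <- list(list(l = 0L, center = c(0.5, -0.2, 1), exp = a, coef = 1, atom = 1L),
             list(l = 0L, center = c(0.5, -0.2, 1), exp = b, coef = 1, atom = 1L))
  tess <- list(centers = matrix(c(0.5, -0.2, 1), 1), omega = w, N = N,
               normal = matrix(c(0, 0, 1), 1))
  bas <- structure(list(shells = sh, nbf = 2L), class = "hipres_basis")
  g <- g_integrals(bas, tess)
  expect_equal(g[1, 2, 1], N * (pi / (a + b + w))^1.5, tolerance = 1e-14)
  # concentric s x s: f vanishes by symmetry, and dg/dw has the
  # differentiated closed form -N (3/2) pi^{3/2} (a+b+w)^{-5/2}
  expect_lt(abs(f_integrals(bas, tess)[1, 2, 1]), 1e-15)
  dg <- exponent_derivative_integrals(bas, tess)$dg[1, 2, 1]
  expect_equal(dg, -N * 1.5 * pi^1.5 * (a + b + w)^-2.5, tolerance = 1e-12)
})

test_that("integrals decay below 1e-15 for far-separated tesserae", {
  set.seed(41)
  sh <- list(rand_shell(1), rand_shell(2, 2L))
  bas <- structure(list(shells = sh, nbf = 9L), class = "hipres_basis")
  tess <- rand_tessera()
  tess$centers <- matrix(c(50, 0, 0), 1)
  expect_lt(max(abs(g_integrals(bas, tess))), 1e-15)
  expect_lt(max(abs(f_integrals(bas, tess))), 1e-15)
  d <- exponent_derivative_integrals(bas, tess)
  expect_lt(max(abs(d$dg)), 1e-15)
  expect_lt(max(abs(d$df)), 1e-15)
})

test_that("blocks are symmetric under bra-ket exchange and linear in the normal", {
  set.seed(42)
  for (rep in 1:4) {
    sh <- list(rand_shell(sample(0:3, 1)), rand_shell(sample(0:3, 1), 2L))
    n <- sum(vapply(sh, function(s) ((s$l + 1) * (s$l + 2)) %/% 2, 0))
    bas <- structure(list(shells = sh, nbf = n), class = "hipres_basis")
    tess <- rand_tessera()
    g <- g_integrals(bas, tess)[, , 1]
    f <- f_integrals(bas, tess)[, , 1]
    expect_lt(max(abs(g - t(g))), 1e-14 * max(abs(g)))
    expect_lt(max(abs(f - t(f))), 1e-13 * max(1, max(abs(f))))
    tneg <- tess; tneg$normal <- -tess$normal
    expect_equal(f_integrals(bas, tneg)[, , 1], -f, tolerance = 1e-14)
  }
})

test_that("center-derivative blocks obey translational invariance and match finite differences", {
  set.seed(43)
  sh <- list(rand_shell(1), rand_shell(2, 2L))
  n <- 3 + 6
  bas <- structure(list(shells = sh, nbf = n), class = "hipres_basis")
  tess <- rand_tessera()
  d <- bra_derivative_integrals(bas, tess)
  expect_lt(max(abs(d$dgdA + d$dgdB + d$dgdC)), 1e-12)
  expect_lt(max(abs(d$dfdA + d$dfdB + d$dfdC)), 1e-12)
  # bra-center finite difference on the (shell1, shell2) slice
  h <- 1e-5
  ra <- 1:3; rb <- 4:9
  for (dim in 1:3) {
    shp <- sh; shp[[1]]$center[dim] <- shp[[1]]$center[dim] + h
    shm <- sh; shm[[1]]$center[dim] <- shm[[1]]$center[dim] - h
    bp <- structure(list(shells = shp, nbf = n), class = "hipres_basis")
    bm <- structure(list(shells = shm, nbf = n), class = "hipres_basis")
    fd <- (g_integrals(bp, tess) - g_integrals(bm, tess))[ra, rb, 1] / (2 * h)
    expect_lt(max(abs(fd - d$dgdA[ra, rb, 1, dim])), 1e-7)
    fdf <- (f_integrals(bp, tess) - f_integrals(bm, tess))[ra, rb, 1] / (2 * h)
    expect_lt(max(abs(fdf - d$dfdA[ra, rb, 1, dim])), 1e-7)
  }
})

test_that("identical s shells at one center have equal bra and ket derivatives", {
  set.seed(44)
  ctr <- rnorm(3)
  sh <- list(list(l = 0L, center = ctr, exp = 0.9, coef = 1, atom = 1L),
             list(l = 0L, center = ctr, exp = 0.9, coef = 1, atom = 1L))
  bas <- structure(list(shells = sh, nbf = 2L), class = "hipres_basis")
  tess <- rand_tessera()
  d <- bra_derivative_integrals(bas, tess)
  expect_equal(d$dgdA[1, 2, 1, ], d$dgdB[1, 2, 1, ], tolerance = 1e-12)
  expect_equal(d$dfdA[1, 2, 1, ], d$dfdB[1, 2, 1, ], tolerance = 1e-12)
})

test_that("screening bounds are conservative and screening is bit-exact", {
  set.seed(45)
  fx <- make_fixture("h2o")
  bas <- load_basis(fx$mol)
  cav <- build_vdw_cavity(fx$mol, grid_points = 26)
  sc <- screen_batches(bas, cav, threshold = 1e-12)
  g <- g_integrals(bas, cav)
  f <- f_integrals(bas, cav)
  # per (shell pair, tessera) true maxima never exceed the bound
  nsh <- length(bas$shells)
  offs <- c(0, cumsum(vapply(bas$shells, function(s) ((s$l + 1) * (s$l + 2)) %/% 2, 0)))
  for (i in seq_len(nsh)) for (j in seq_len(nsh)) {
    ri <- (offs[i] + 1):offs[i + 1]; rj <- (offs[j] + 1):offs[j + 1]
    gi <- apply(abs(g[ri, rj, , drop = FALSE]), 3, max)
    fi <- apply(abs(f[ri, rj, , drop = FALSE]), 3, max)
    expect_true(all(gi <= sc$bound_g[i, j, ] + 1e-300))
    expect_true(all(fi <= sc$bound_f[i, j, ]))
  }
  # threshold 0 never skips; with a threshold, kept values are unchanged
  D <- diag(bas$nbf)
  a0 <- compute_aux_vectors(bas, D, cav, threshold = 0)
  a1 <- compute_aux_vectors(bas, D, cav, threshold = 1e-12)
  expect_equal(a0$skipped, 0)
  expect_lt(max(abs(a0$gt - a1$gt)), 1e-12)
  expect_lt(max(abs(a0$ft - a1$ft)), 1e-12)
  # a distant batch is skipped and its true contribution is below threshold
  far <- list(centers = matrix(c(50, 0, 0), 1), omega = 1, N = (1 / pi)^1.5,
              normal = matrix(c(1, 0, 0), 1))
  scf <- screen_batches(bas, far, threshold = 1e-12)
  expect_true(all(scf$skip))
  expect_lt(max(abs(g_integrals(bas, far))), 1e-12)
})

test_that("angular momenta beyond the supported maximum are rejected", {
  sh <- list(list(l = 5L, center = c(0, 0, 0), exp = 1, coef = 1, atom = 1L))
  bas <- structure(list(shells = sh, nbf = 21L), class = "hipres_basis")
  expect_error(g_integrals(bas, rand_tessera()), "angular momentum")
})
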