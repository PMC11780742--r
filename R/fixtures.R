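## Deterministic test geometries.  The crevice fixture hinges two benzene
## rings into a pincer-like wedge: tesserae deep in the wedge interior
## have outward normals pointing toward the opposite ring's density, which
## flips the sign of the density-gradient contraction and produces the
## negative-amplitude diagnostic on the plain van der Waals surface.  A
## parallel sandwich does not do this -- it has no concave pocket -- so
## the fixture is a wedge, closest inter-ring carbon contact 3.2 Angstrom.

#' Built-in test fixtures
#'
#' Returns a named, deterministic geometry plus the calculation settings
#' used with it throughout the package.
#'
#' Available fixtures: `h2` (0.74 Angstrom bond), `h2o` (equilibrium-like
#' water), `ch4` (tetrahedral methane), `ne2` (neon dimer at 3.1
#' Angstrom), `benzene_dimer_crevice` (two eclipsed benzenes stacked at
#' 3.2 Angstrom with the crevice-prone radii H 1.4 / C 2.1 Angstrom).
#'
#' @param name fixture name.
#' @return list with `name`, `mol`, `basis`, `radii`, `grid_points`,
#'   `r_ext`, `pressures`.
#' @export
make_fixture <- function(name) {
  fx <- switch(name,
    h2 = list(
      mol = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74))),
      radii = NULL, grid_points = 110, pressures = c(0, 5, 10, 20, 50)),
    h2o = {
      r <- 0.9572; a <- 104.52 * pi / 180
      list(
        mol = molecule(c("O", "H", "H"),
                       rbind(c(0, 0, 0),
                             c(r * sin(a / 2), 0, r * cos(a / 2)),
                             c(-r * sin(a / 2), 0, r * cos(a / 2)))),
        radii = NULL, grid_points = 110, pressures = c(0, 1, 5, 10, 20))
    },
    ch4 = {
      d <- 1.089 / sqrt(3)
      list(
        mol = molecule(c("C", "H", "H", "H", "H"),
                       rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d),
                             c(-d, d, -d), c(-d, -d, d))),
        radii = NULL, grid_points = 110, pressures = c(0, 5, 25))
    },
    ne2 = list(
      mol = molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(0, 0, 3.1))),
      radii = NULL, grid_points = 110, pressures = c(0, 1, 2, 3, 4, 5)),
    benzene_dimer_crevice = {
      rc <- 1.39; rh <- rc + 1.09
      ang <- (0:5) * pi / 3
      ring <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                    cbind(rh * cos(ang), rh * sin(ang), 0))
      theta <- 0.3  # hinge angle (rad) opening the wedge
      Ry <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
                  c(-sin(theta), 0, cos(theta)))
      r2 <- ring %*% t(Ry)
      ## raise the tilted ring until the closest inter-ring C-C contact
      ## is 3.2 Angstrom
      gapf <- function(h) {
        r2h <- sweep(r2, 2, c(0, 0, -h))
        min(as.matrix(stats::dist(rbind(ring[1:6, ], r2h[1:6, ])))[1:6, 7:12]) - 3.2
      }
      h <- stats::uniroot(gapf, c(0.1, 12))$root
      list(
        mol = molecule(rep(c(rep("C", 6), rep("H", 6)), 2),
                       rbind(ring, sweep(r2, 2, c(0, 0, -h)))),
        radii = c(H = 1.4, C = 2.1), grid_points = 110,
        pressures = c(0, 5, 10))
    },
    stop("unknown fixture: ", name)
  )
  c(list(name = name, basis = "sto-3g", r_ext = 0.25), fx)
}

#' @rdname make_fixture
#' @return for `fixture_names`, the available fixture names.
#' @export
fixture_names <- function() c("h2", "h2o", "ch4", "ne2", "benzene_dimer_crevice")
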