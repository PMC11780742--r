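## Discretized van der Waals cavities.
##
## Each atomic sphere carries a Lebedev grid; a grid point survives with a
## smooth switching weight that fades it out as it penetrates neighboring
## spheres.  The switching factor per neighbor is the quintic smoothstep
## S(t) = t^3 (10 - 15 t + 6 t^2) of t = (d - r)/delta + 1/2, where d is
## the distance of the point to the neighbor's center, r the neighbor's
## sphere radius and delta = 0.1 r the switching-region width; points on
## the neighbor's surface therefore carry factor 1/2, points buried deeper
## than delta/2 fade to 0.  The weight is the product over all neighbors,
## and tesserae below a discard cutoff are removed.
##
## With the outer-cavity correction (OCC) a second surface with all radii
## enlarged by r_ext is built; the one-to-one Lebedev mapping lets the
## OUTER point's switching weight be assigned to the inner tessera, which
## screens away crevice regions (at the price of small holes where the
## outer point is buried but the inner one is not).

.weight_cutoff <- 1e-8
.switch_frac <- 0.1

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (10 - 15 * t + 6 * t^2)
}

smoothstep_d <- function(t) {
  out <- numeric(length(t))
  i <- t > 0 & t < 1
  out[i] <- 30 * t[i]^2 * (1 - t[i])^2
  out
}

## switching weight of points `pts` (n x 3, bohr) with respect to the
## spheres of atoms `atoms_xyz` with radii `radii` (bohr), excluding atom
## `self`.  Returns the weights and, on request, d(weight)/d(R) pieces.
switch_weights <- function(pts, self, atoms_xyz, radii) {
  w <- rep(1, nrow(pts))
  for (j in seq_len(nrow(atoms_xyz))) {
    if (j == self) next
    d <- sqrt(rowSums((pts - matrix(atoms_xyz[j, ], nrow(pts), 3, byrow = TRUE))^2))
    delta <- .switch_frac * radii[j]
    w <- w * smoothstep((d - radii[j]) / delta + 0.5)
  }
  w
}

#' Build a discretized van der Waals cavity
#'
#' Places a Lebedev grid on the van der Waals sphere of every real atom,
#' weights each point by the product of smooth switching factors of all
#' neighboring spheres, and discards points whose weight falls below the
#' cutoff `1e-8`.  Tessera areas are
#' `(Lebedev weight) * (switching weight) * 4 pi r^2`; normals point
#' radially outward from the parent atom.  Each tessera Gaussian's
#' exponent follows from the edge-halving condition
#' `omega = pi log(2) / area` and its normalization is
#' `N = (omega/pi)^(3/2)` so the Gaussian integrates to one.
#'
#' With `r_ext > 0` the outer-cavity correction is applied: the switching
#' weights are evaluated on a second surface with all radii enlarged by
#' `r_ext`, and assigned to the inner tesserae through the one-to-one
#' Lebedev mapping.
#'
#' @param mol a `hipres_mol`.
#' @param radii named vector of per-element sphere radii in Angstrom
#'   (default: Bondi radii).
#' @param grid_points Lebedev points per atom (see [lebedev_orders()]).
#' @param r_ext outer-cavity-correction extension radius in Angstrom;
#'   0 disables the correction.
#' @return an object of class `gost_cavity` with matrices/vectors
#'   `centers` (bohr), `area` (bohr^2), `normal`, `omega` (bohr^-2),
#'   `N` (bohr^-3), `weight`, `parent`, and the construction parameters.
#' @export
build_vdw_cavity <- function(mol, radii = NULL, grid_points = 110, r_ext = 0) {
  if (r_ext < 0) stop("r_ext must be >= 0")
  if (is.null(radii)) radii <- default_vdw_radii(unique(mol$symbols[!mol$ghost]))
  real <- which(!mol$ghost)
  if (length(real) < 1) stop("cavity requires at least one real atom")
  miss <- setdiff(mol$symbols[real], names(radii))
  if (length(miss)) stop("no cavity radius for element(s): ", paste(miss, collapse = ", "))
  grid <- lebedev_grid(grid_points)
  r_at <- radii[mol$symbols[real]] * bohr_per_angstrom
  rx <- r_ext * bohr_per_angstrom
  axyz <- mol$xyz[real, , drop = FALSE]

  centers <- NULL; area <- NULL; nrm <- NULL; wt <- NULL; parent <- NULL; lebw <- NULL
  for (k in seq_along(real)) {
    pts_in <- axyz[rep(k, nrow(grid$points)), , drop = FALSE] + grid$points * r_at[k]
    if (rx > 0) {
      pts_sw <- axyz[rep(k, nrow(grid$points)), , drop = FALSE] + grid$points * (r_at[k] + rx)
      w <- switch_weights(pts_sw, k, axyz, r_at + rx)
    } else {
      w <- switch_weights(pts_in, k, axyz, r_at)
    }
    keep <- w >= .weight_cutoff
    if (!any(keep)) next
    centers <- rbind(centers, pts_in[keep, , drop = FALSE])
    nrm <- rbind(nrm, grid$points[keep, , drop = FALSE])
    a <- grid$weights[keep] * w[keep] * 4 * pi * r_at[k]^2
    area <- c(area, a)
    wt <- c(wt, w[keep])
    lebw <- c(lebw, grid$weights[keep])
    parent <- c(parent, rep(real[k], sum(keep)))
  }
  omega <- pi * log(2) / area
  structure(list(
    centers = centers, area = area, normal = nrm, omega = omega,
    N = (omega / pi)^1.5, weight = wt, lebw = lebw, parent = parent,
    n = length(area),
    params = list(radii = radii, grid_points = grid_points, r_ext = r_ext,
                  type = if (rx > 0) "vdw_occ" else "vdw"),
    mol = mol
  ), class = "gost_cavity")
}

#' Apply the outer-cavity correction to a cavity's construction
#'
#' Rebuilds the cavity of `cavity$mol` with the same radii and grid but
#' with switching weights taken from a surface extended by `r_ext`
#' ("small holes" where the outer point is screened out are simply
#' dropped).  `r_ext = 0` reproduces the plain van der Waals cavity.
#'
#' @param cavity a `gost_cavity`.
#' @param r_ext extension radius in Angstrom (>= 0).
#' @return a `gost_cavity`.
#' @export
apply_occ <- function(cavity, r_ext) {
  if (r_ext < 0) stop("r_ext must be >= 0")
  build_vdw_cavity(cavity$mol, radii = cavity$params$radii,
                   grid_points = cavity$params$grid_points, r_ext = r_ext)
}

#' @export
print.gost_cavity <- function(x, ...) {
  cat(sprintf("<gost_cavity> %s: %d tesserae on %d spheres, total area %.4f bohr^2\n",
              x$params$type, x$n, length(unique(x$parent)), sum(x$area)))
  invisible(x)
}

#' Dump a cavity as a plain-text table
#'
#' Writes tessera index, parent atom, center (bohr), area (bohr^2),
#' outward normal and switching weight, for debugging and tests.
#'
#' @param cavity a `gost_cavity`.
#' @param path output file path.
#' @export
cavity_dump <- function(cavity, path) {
  df <- data.frame(index = seq_len(cavity$n), parent = cavity$parent,
                   x = cavity$centers[, 1], y = cavity$centers[, 2], z = cavity$centers[, 3],
                   area = cavity$area,
                   nx = cavity$normal[, 1], ny = cavity$normal[, 2], nz = cavity$normal[, 3],
                   weight = cavity$weight)
  utils::write.table(format(df, digits = 12), path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analytic nuclear derivatives of the cavity parametrization
#'
#' Differentiates tessera areas through the switching weights (for the
#' outer-cavity correction: through the outer-surface switch) with respect
#' to all real-atom displacements.  Tessera centers are rigidly attached
#' to their parent atom, so `d r_j / d R_I = delta_{I,parent} * Identity`;
#' only the area derivative table is returned explicitly.
#'
#' @param cavity a `gost_cavity`.
#' @param mol the molecule the cavity was built for (defaults to the one
#'   stored in the cavity).
#' @return array `darea` of dimension (n_tess, n_atom, 3) in bohr^2/bohr.
#' @export
cavity_derivatives <- function(cavity, mol = cavity$mol) {
  real <- which(!mol$ghost)
  axyz <- mol$xyz[real, , drop = FALSE]
  radii <- cavity$params$radii[mol$symbols[real]] * bohr_per_angstrom
  rx <- cavity$params$r_ext * bohr_per_angstrom
  rsw <- radii + rx   # radii of the surface carrying the switch
  natom <- length(mol$symbols)
  darea <- array(0, dim = c(cavity$n, natom, 3))
  ## switching points: inner centers shifted outward for OCC
  kloc <- match(cavity$parent, real)
  pts <- cavity$centers + cavity$normal * rx
  base <- cavity$lebw * 4 * pi * radii[kloc]^2   # area without switching
  for (j in seq_len(cavity$n)) {
    k <- kloc[j]
    ## per-neighbor smoothstep factors
    dvec <- sweep(axyz, 2, pts[j, ], "-") * (-1)   # pts - R_J
    dist <- sqrt(rowSums(dvec^2))
    tval <- (dist - rsw) / (.switch_frac * rsw) + 0.5
    s <- smoothstep(tval); s[k] <- 1
    sd <- smoothstep_d(tval); sd[k] <- 0
    w <- prod(s)
    if (w <= 0) next
    for (J in seq_len(nrow(axyz))) {
      if (J == k || sd[J] == 0) next
      pref <- base[j] * (w / s[J]) * sd[J] / (.switch_frac * rsw[J])
      u <- dvec[J, ] / dist[J]          # d(dist)/d(pts)
      ## pts moves with the parent atom; dist also depends on R_J directly
      darea[j, real[k], ] <- darea[j, real[k], ] + pref * u
      darea[j, real[J], ] <- darea[j, real[J], ] - pref * u
    }
  }
  darea
}
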