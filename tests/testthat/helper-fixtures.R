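# Shared test helpers: random shell generation, quadrature-oracle wrappers
# for the three-center integrals, and small prebuilt systems.

ns <- getNamespace("hipres")
ang2bohr <- 1.8897261246

rand_shell <- function(l, atom = 1L, nprim = 2) {
  list(l = as.integer(l), center = stats::rnorm(3),
       exp = stats::runif(nprim, 0.2, 2.5),
       coef = stats::runif(nprim, 0.4, 1.2), atom = as.integer(atom))
}

cart_components <- function(l) {
  out <- NULL
  for (lx in l:0) for (ly in (l - lx):0) out <- rbind(out, c(lx, ly, l - lx - ly))
  out
}

rand_tessera <- function(omega = stats::runif(1, 0.4, 4)) {
  nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
  list(centers = matrix(stats::rnorm(3, sd = 1.5), 1), omega = omega,
       N = (omega / pi)^1.5, normal = matrix(nrm, 1))
}

# quadrature-oracle value of <mu|(r-C)^pow G_j|nu> for one component pair,
# summed over the primitive contraction
oracle_overlap <- function(sa, sb, ia, ib, tess, pow = c(0, 0, 0)) {
  ca <- cart_components(sa$l)[ia, ]; cb <- cart_components(sb$l)[ib, ]
  v <- 0
  for (ka in seq_along(sa$exp)) for (kb in seq_along(sb$exp))
    v <- v + sa$coef[ka] * sb$coef[kb] * tess$N *
      quadrature_oracle(rbind(sa$center, sb$center, tess$centers[1, ]),
                        c(sa$exp[ka], sb$exp[kb], tess$omega),
                        rbind(ca, cb, pow))
  v
}

oracle_g <- function(sa, sb, ia, ib, tess) oracle_overlap(sa, sb, ia, ib, tess)

# f = n . grad_C g; the gradient brings down 2*omega*(r-C)_d
oracle_f <- function(sa, sb, ia, ib, tess) {
  e3 <- diag(3)
  sum(vapply(1:3, function(d)
    tess$normal[1, d] * 2 * tess$omega *
      oracle_overlap(sa, sb, ia, ib, tess, e3[d, ]), 0))
}

# dg/domega at fixed N = -<mu| |r-C|^2 G |nu>
oracle_gw <- function(sa, sb, ia, ib, tess) {
  e3 <- 2 * diag(3)
  -sum(vapply(1:3, function(d) oracle_overlap(sa, sb, ia, ib, tess, e3[d, ]), 0))
}

# df/domega at fixed N = sum_d n_d [2 I_d - 2 omega <(r-C)_d |r-C|^2>]
oracle_fw <- function(sa, sb, ia, ib, tess) {
  e3 <- diag(3)
  v <- 0
  for (d in 1:3) {
    I1 <- oracle_overlap(sa, sb, ia, ib, tess, e3[d, ])
    I3 <- sum(vapply(1:3, function(e)
      oracle_overlap(sa, sb, ia, ib, tess, e3[d, ] + 2 * e3[e, ]), 0))
    v <- v + tess$normal[1, d] * (2 * I1 - 2 * tess$omega * I3)
  }
  v
}

bond_length_ang <- function(mol, i = 1, j = 2) {
  sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2)) / ang2bohr
}

tight_scf <- function(mol, ...) {
  run_scf(mol, conv_energy = 1e-11, conv_orb = 1e-8, ...)
}
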