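## Independent brute-force oracles used by the test suite: a Gauss-Hermite
## product quadrature for integrals of Gaussian products, and a central
## finite-difference engine for derivatives.  These share no code with the
## Hermite-recursion integral engine they are used to validate.

## Gauss-Hermite nodes/weights for weight exp(-x^2) via the Golub-Welsch
## eigenvalue method (symmetric Jacobi matrix).
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(k / 2)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  .gh_cache[[key]] <- list(nodes = x[ord], weights = w[ord])
  .gh_cache[[key]]
}

#' Quadrature oracle for products of Cartesian Gaussians
#'
#' Computes the 3-d integral of a product of up to three Cartesian
#' Gaussian factors `(x-Ax)^px (y-Ay)^py (z-Az)^pz exp(-a |r-A|^2)` by a
#' Gauss-Hermite product rule centered at the combined Gaussian center.
#' Because the integrand is a polynomial times the combined Gaussian, the
#' rule is exact once the order covers the polynomial degree; the order is
#' escalated until two successive orders agree to the requested tolerance,
#' and an error is raised otherwise (never a silent inaccurate value).
#'
#' @param centers matrix (m x 3) of Gaussian centers (bohr).
#' @param exponents length-m vector of Gaussian exponents.
#' @param powers matrix (m x 3) of per-dimension polynomial powers.
#' @param coef overall multiplicative constant.
#' @param tol relative agreement required between successive orders.
#' @return the integral value.
#' @export
quadrature_oracle <- function(centers, exponents, powers, coef = 1, tol = 1e-12) {
  centers <- matrix(centers, ncol = 3)
  powers <- matrix(powers, ncol = 3)
  m <- nrow(centers)
  stopifnot(length(exponents) == m, nrow(powers) == m)
  s <- sum(exponents)
  Q <- colSums(centers * exponents) / s
  ## constant part of the exponent: sum a_i |r-A_i|^2 = s|r-Q|^2 + c0
  c0 <- sum(exponents * rowSums(centers^2)) - s * sum(Q^2)
  eval1d <- function(n, dim) {
    gh <- gauss_hermite(n)
    x <- Q[dim] + gh$nodes / sqrt(s)
    poly <- rep(1, n)
    for (i in seq_len(m)) poly <- poly * (x - centers[i, dim])^powers[i, dim]
    sum(gh$weights * poly) / sqrt(s)
  }
  total <- function(n) coef * exp(-c0) * prod(vapply(1:3, function(d) eval1d(n, d), 0))
  n <- max(4, ceiling(sum(powers) / 2) + 2)
  v1 <- total(n)
  for (rep in 1:8) {
    n <- n + 4
    v2 <- total(n)
    if (abs(v2 - v1) <= tol * max(abs(v2), 1e-300) + 1e-16) return(v2)
    v1 <- v2
  }
  stop("quadrature oracle failed to reach tolerance")
}

#' Finite-difference oracle
#'
#' Central-difference derivative of a scalar function with optional
#' Richardson step-halving consistency check: if the estimates at step h
#' and h/2 drift apart by more than a factor 10 of the expected reduction
#' the result is flagged unreliable.
#'
#' @param f scalar function of a numeric vector.
#' @param x evaluation point.
#' @param step finite-difference step.
#' @param check run the step-halving consistency check.
#' @return list with `grad` (same length as `x`) and `reliable`.
#' @export
finite_difference_oracle <- function(f, x, step = 1e-5, check = FALSE) {
  g <- function(h) {
    vapply(seq_along(x), function(i) {
      e <- numeric(length(x)); e[i] <- h
      (f(x + e) - f(x - e)) / (2 * h)
    }, 0)
  }
  grad <- g(step)
  reliable <- TRUE
  if (check) {
    g2 <- g(step / 2)
    drift <- abs(grad - g2)
    scale <- pmax(abs(g2), 1e-10)
    reliable <- all(drift / scale < 1e-2 | drift < 1e-9)
    grad <- g2
  }
  list(grad = grad, reliable = reliable)
}
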