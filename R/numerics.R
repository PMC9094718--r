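# Small numerical-integration helpers (no external dependency provides the
# bivariate-normal and latent-factor integrals needed here).

# Golub-Welsch: Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (a + b) / 2 + (b - a) / 2 * x, weights = (b - a) / 2 * w)
}

# Gauss-Hermite for integrals against the standard normal density:
# E[f(W)] ~ sum w_i f(x_i) with W ~ N(0,1).
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  beta <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  # weights for weight function exp(-x^2); rescale to N(0,1)
  list(nodes = e$values * sqrt(2), weights = e$vectors[1, ]^2)
}

#' Bivariate standard normal rectangle probability
#'
#' `P(Z1 <= a, Z2 <= b)` for standard normal margins with correlation `rho`,
#' computed from the correlation-path integral
#' `Phi2(a, b, rho) = Phi(a) Phi(b) + int_0^rho phi2(a, b; r) dr`
#' with Gauss-Legendre quadrature on the path. Vectorised over `a`, `b`.
#'
#' @param a,b numeric vectors of upper limits
#' @param rho scalar correlation in (-1, 1)
#' @param nodes number of quadrature nodes
#' @return vector of probabilities
#' @export
pbinorm <- function(a, b, rho, nodes = 24) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  base <- pnorm(a) * pnorm(b)
  if (rho == 0) return(base)
  # substitute r = sin(theta): removes the 1/sqrt(1-r^2) endpoint singularity
  gl <- gauss_legendre(nodes, 0, asin(rho))
  acc <- 0
  for (k in seq_len(nodes)) {
    sth <- sin(gl$nodes[k])
    cth2 <- cos(gl$nodes[k])^2
    dens <- exp(-(a^2 - 2 * sth * a * b + b^2) / (2 * cth2)) / (2 * pi)
    acc <- acc + gl$weights[k] * dens
  }
  pmin(1, pmax(0, base + acc))
}
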