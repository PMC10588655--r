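# Gaussian quadrature rules via Golub-Welsch (symmetric tridiagonal Jacobi
# matrix eigendecomposition). Only the small fixed orders used internally.

#' @noRd
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  # total mass of the weight function on [-1, 1] is 2
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' @noRd
gauss_legendre_01 <- function(n) {
  gl <- gauss_legendre(n)
  list(nodes = (gl$nodes + 1) / 2, weights = gl$weights / 2)
}

#' @noRd
gauss_laguerre <- function(n) {
  k <- seq_len(n - 1)
  J <- diag(2 * seq_len(n) - 1)
  J[cbind(k, k + 1)] <- k
  J[cbind(k + 1, k)] <- k
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = e$vectors[1, ord]^2)
}
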