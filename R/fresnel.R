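# Normalized Fresnel integrals
#   C(u) = int_0^u cos(pi t^2 / 2) dt,  S(u) = int_0^u sin(pi t^2 / 2) dt
# evaluated to near machine precision without external special-function
# libraries. Small arguments use the (rapidly convergent, cancellation-free)
# Maclaurin series; larger arguments use the complementary integral
#   E(u) = int_0^u exp(-i pi t^2 / 2) dt = (1 - i)/2 - T(u)
# with the tail T(u) rotated onto a non-oscillatory Laplace contour,
#   T(u) = -i e^{-i pi u^2/2} int_0^inf e^{-pi r/2} / (2 sqrt(u^2 - i r)) dr,
# and the r-integral done by fixed-order Gauss-Laguerre quadrature.

.fresnel_env <- new.env(parent = emptyenv())

.fresnel_laguerre <- function() {
  if (is.null(.fresnel_env$gla)) .fresnel_env$gla <- gauss_laguerre(48L)
  .fresnel_env$gla
}

# Maclaurin series, vectorized over u; terms alternate but at u <= 1.5 the
# largest term is the first, so there is no cancellation trouble.
#   C: (-1)^k (pi/2)^(2k)   u^(4k+1) / ((2k)!  (4k+1))
#   S: (-1)^k (pi/2)^(2k+1) u^(4k+3) / ((2k+1)! (4k+3))
.fresnel_series_direct <- function(u, nmax = 24L) {
  k <- 0:nmax
  cc <- (-1)^k * (pi / 2)^(2 * k) / (factorial(2 * k) * (4 * k + 1))
  Cv <- as.vector(cc %*% exp(outer(4 * k + 1, log(u))))
  ss <- (-1)^k * (pi / 2)^(2 * k + 1) / (factorial(2 * k + 1) * (4 * k + 3))
  Sv <- as.vector(ss %*% exp(outer(4 * k + 3, log(u))))
  list(C = Cv, S = Sv)
}

.fresnel_tail <- function(u) {
  gla <- .fresnel_laguerre()
  # int_0^inf e^{-pi r/2} g(r) dr = (2/pi) sum w_j g(2 x_j / pi)
  r <- 2 * gla$nodes / pi
  # g(r) = 1 / (2 sqrt(u^2 - i r)); outer over (nodes, u)
  z <- outer(-1i * r, u^2, `+`)        # u^2 - i r
  g <- 1 / (2 * sqrt(z))
  integral <- as.vector((2 / pi) * (gla$weights %*% g))
  Tu <- -1i * exp(-1i * pi * u^2 / 2) * integral
  E <- (1 - 1i) / 2 - Tu
  list(C = Re(E), S = -Im(E))
}

#' Fresnel integrals C(u) and S(u)
#'
#' Normalized Fresnel cosine and sine integrals,
#' \eqn{C(u)=\int_0^u \cos(\pi t^2/2)\,dt} and
#' \eqn{S(u)=\int_0^u \sin(\pi t^2/2)\,dt}, vectorized over \code{u}.
#' These enter the closed-form intravascular (blood) compartment of the
#' qBOLD asymmetric-spin-echo signal model.
#'
#' @param u numeric vector of arguments (any sign; C and S are odd).
#' @return list with numeric components \code{C} and \code{S}.
#' @export
#' @examples
#' fresnel_cs(1)    # C(1) ~ 0.7799, S(1) ~ 0.4383
fresnel_cs <- function(u) {
  stopifnot(is.numeric(u), all(is.finite(u)))
  sgn <- sign(u)
  a <- abs(u)
  C <- S <- numeric(length(a))
  small <- a <= 1.5
  if (any(small)) {
    az <- a[small]
    pos <- az > 0
    res <- list(C = numeric(length(az)), S = numeric(length(az)))
    if (any(pos)) {
      r <- .fresnel_series_direct(az[pos])
      res$C[pos] <- r$C
      res$S[pos] <- r$S
    }
    C[small] <- res$C
    S[small] <- res$S
  }
  if (any(!small)) {
    r <- .fresnel_tail(a[!small])
    C[!small] <- r$C
    S[!small] <- r$S
  }
  list(C = sgn * C, S = sgn * S)
}
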