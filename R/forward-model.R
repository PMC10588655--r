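# Two-compartment qBOLD forward model for asymmetric spin echo (ASE) signals.
#
# A voxel's extravascular (tissue) signal decays with the irreversible rate
# R2t at the fixed echo time and, away from the spin echo, with a reversible
# component governed by the characteristic frequency
#   delta_omega = (4 pi / 3) gamma B0 dchi0 Hct OEF
# so that R2' = DBV * delta_omega. The static-dephasing tissue signal has a
# quadratic-exponent regime at short tau and a linear-exponent regime at long
# tau, with the boundary at Tc = 1.76 / delta_omega. The intravascular
# (blood) compartment is the powder average over randomly oriented vessels,
# which has a closed form in Fresnel integrals. Everything here is
# vectorized over voxels and over tau by recycling.

#' Characteristic dephasing frequency
#'
#' \code{delta_omega = (4*pi/3) * gamma * b0 * dchi0 * hct * oef}, the
#' frequency offset at the surface of a vessel containing deoxygenated blood;
#' zero iff \code{oef} is zero.
#'
#' @param oef oxygen extraction fraction, fraction in [0, 1]; vectorized.
#' @param const \code{\link{tissue_constants}}.
#' @param b0 field strength in tesla.
#' @return characteristic frequency in s^-1.
#' @export
#' @examples
#' delta_omega(0.4, tissue_constants(), 3)  # ~ 142 s^-1
delta_omega <- function(oef, const = tissue_constants(), b0 = 3) {
  if (any(oef < 0)) stop("oef must be non-negative")
  if (any(oef > 1)) stop("oef must be <= 1")
  (4 * pi / 3) * const$gamma * b0 * const$dchi0 * const$hct * oef
}

#' Quantities derived from the dephasing frequency
#'
#' @param oef,dbv physiological fractions; vectorized.
#' @inheritParams delta_omega
#' @return list with \code{delta_omega} (s^-1), \code{r2p} (= dbv *
#'   delta_omega, s^-1), \code{tc_small} (= 1/delta_omega, s) and
#'   \code{tc_boundary} (= 1.76 * tc_small, s).
#' @export
dephasing_derived <- function(oef, dbv, const = tissue_constants(), b0 = 3) {
  dw <- delta_omega(oef, const, b0)
  list(delta_omega = dw, r2p = dbv * dw,
       tc_small = 1 / dw, tc_boundary = 1.76 / dw)
}

#' Invert R2' = DBV * delta_omega for OEF
#'
#' \code{oef = 3 * r2p / (4*pi * gamma * b0 * dchi0 * hct * dbv)}; exact
#' inverse of \code{\link{delta_omega}} composed with \code{r2p = dbv * dw}.
#'
#' @param r2p reversible relaxation rate, s^-1; vectorized.
#' @param dbv deoxygenated blood volume fraction; vectorized.
#' @inheritParams delta_omega
#' @return OEF as a fraction (NA where dbv == 0).
#' @export
oef_from_r2p_dbv <- function(r2p, dbv, const = tissue_constants(), b0 = 3) {
  out <- 3 * r2p / (4 * pi * const$gamma * b0 * const$dchi0 * const$hct * dbv)
  out[dbv == 0] <- NA_real_
  out
}

#' Transverse relaxation rate of blood
#'
#' Empirical quadratic dependence on hematocrit and oxygen extraction:
#' \code{16.4*hct + 4.5 + (165.2*hct + 55.7) * oef^2} (s^-1).
#'
#' @param hct fractional hematocrit in (0, 1).
#' @param oef oxygen extraction fraction in [0, 1]; vectorized.
#' @return R2b in s^-1.
#' @export
r2b <- function(hct, oef) {
  if (any(hct <= 0) || any(hct >= 1)) stop("hct must be in (0, 1)")
  if (any(oef < 0) || any(oef > 1)) stop("oef must be in [0, 1]")
  16.4 * hct + 4.5 + (165.2 * hct + 55.7) * oef^2
}

#' Extravascular (tissue) ASE signal
#'
#' Static-dephasing tissue signal at spin-echo displacement \code{tau}:
#' \deqn{S_t = S_0 e^{-R_{2t} TE} e^{-(3/10) DBV (\delta\omega \tau)^2}}
#' for \eqn{\tau < T_c} and
#' \deqn{S_t = S_0 e^{-R_{2t} TE} e^{DBV - DBV \delta\omega \tau}}
#' for \eqn{\tau \ge T_c}, with \eqn{T_c = 1.76/\delta\omega}. The branch is
#' chosen per voxel from that voxel's own \eqn{\delta\omega}; the two
#' asymptotic branches are not blended at the boundary.
#'
#' @param state \code{\link{voxel_state}} (possibly vector-valued).
#' @param const \code{\link{tissue_constants}}.
#' @param proto \code{\link{ase_protocol}} (supplies TE and B0).
#' @param tau spin-echo displacement time(s), seconds, >= 0.
#' @return signal amplitude, recycled over voxels and tau.
#' @export
tissue_signal <- function(state, const = tissue_constants(),
                          proto = ase_protocol(), tau) {
  if (any(tau < 0)) stop("tau must be non-negative")
  dw <- delta_omega(state$oef, const, proto$b0)
  n <- max(length(dw), length(tau), length(state$dbv), length(state$s0))
  dw <- rep_len(dw, n); tau <- rep_len(tau, n)
  dbv <- rep_len(state$dbv, n); s0 <- rep_len(state$s0, n)
  base <- s0 * exp(-const$r2t * proto$te)
  # tau * dw < 1.76 is the short-tau regime; dw = 0 (oef = 0) is always short
  short <- tau * dw < 1.76
  expo <- ifelse(short, -0.3 * dbv * (dw * tau)^2, dbv - dbv * dw * tau)
  base * exp(expo)
}

#' Intravascular (blood) ASE signal
#'
#' Closed-form powder average over randomly oriented vessels:
#' \deqn{S_b(\tau) = e^{-R_{2b} TE + i \delta\omega \tau / 2}
#'   \frac{C(\eta) - i S(\eta)}{\eta}, \quad
#'   \eta = \sqrt{3 \delta\omega \tau / \pi}}
#' with C, S the normalized Fresnel integrals. At \eqn{\tau = 0} the Fresnel
#' factor is taken at its analytic limit 1. The returned value is complex;
#' magnitude ASE images use \code{Mod()} downstream, which makes the sign of
#' the phase factor immaterial.
#'
#' @inheritParams tissue_signal
#' @return complex signal (per unit S0), recycled over voxels and tau.
#' @export
blood_signal <- function(state, const = tissue_constants(),
                         proto = ase_protocol(), tau) {
  if (any(tau < 0)) stop("tau must be non-negative")
  dw <- delta_omega(state$oef, const, proto$b0)
  n <- max(length(dw), length(tau))
  dw <- rep_len(dw, n); tau <- rep_len(tau, n)
  oef <- rep_len(state$oef, n)
  u <- dw * tau
  fac <- fresnel_ratio(u)
  exp(-r2b(const$hct, oef) * proto$te + 1i * u / 2) * fac
}

#' Fresnel powder factor (C(eta) - i S(eta)) / eta
#'
#' The orientation-average factor of the blood signal as a function of
#' \code{u = delta_omega * tau}, with \code{eta = sqrt(3 u / pi)} and the
#' analytic limit 1 at \code{u = 0}.
#'
#' @param u non-negative numeric vector.
#' @return complex vector, modulus <= 1.
#' @export
fresnel_ratio <- function(u) {
  stopifnot(all(u >= 0))
  eta <- sqrt(3 * u / pi)
  out <- rep(1 + 0i, length(u))
  pos <- eta > 0
  if (any(pos)) {
    fr <- fresnel_cs(eta[pos])
    out[pos] <- (fr$C - 1i * fr$S) / eta[pos]
  }
  out
}

#' Numerical powder-average oracle for the blood-signal factor
#'
#' Independent quadrature evaluation of the orientation average
#' \deqn{\int_0^1 \exp(-i \delta\omega \tau (3x^2 - 1)/2) \, dx}
#' used to validate the Fresnel closed form (to which it is mathematically
#' identical up to the \eqn{e^{-R_{2b} TE}} relaxation factor). Composite
#' Simpson quadrature with a convergence check on doubling.
#'
#' @param delta_omega characteristic frequency, s^-1 (scalar).
#' @param tau spin-echo displacement, seconds (scalar).
#' @param n_points number of quadrature points (>= 1000; rounded up to odd).
#' @return complex scalar, modulus <= 1.
#' @export
powder_average_oracle <- function(delta_omega, tau, n_points = 4001L) {
  stopifnot(length(delta_omega) == 1, length(tau) == 1, n_points >= 1000)
  u <- delta_omega * tau
  f <- function(x) exp(-1i * u * (3 * x^2 - 1) / 2)
  simpson <- function(n) {
    if (n %% 2 == 0) n <- n + 1L           # Simpson needs an odd point count
    x <- seq(0, 1, length.out = n)
    w <- rep(c(2, 4), length.out = n); w[1] <- w[n] <- 1
    h <- x[2] - x[1]
    sum(w * f(x)) * h / 3
  }
  v1 <- simpson(as.integer(n_points))
  v2 <- simpson(2L * as.integer(n_points))
  if (abs(v2 - v1) > 1e-8 * max(abs(v2), 1)) {
    stop("powder average quadrature did not converge; increase n_points")
  }
  v2
}

#' Total two-compartment ASE signal
#'
#' Magnitude-valued sum of the compartments,
#' \deqn{S_{total}(\tau) = S_0 [ DBV |S_b(\tau)| + (1 - DBV) S_t(\tau)/S_0 ]}
#' where the tissue term carries S0 internally. At \code{dbv = 0} this equals
#' \code{\link{tissue_signal}} exactly.
#'
#' @inheritParams tissue_signal
#' @return signal amplitude, recycled over voxels and tau.
#' @export
total_signal <- function(state, const = tissue_constants(),
                         proto = ase_protocol(), tau) {
  st <- tissue_signal(state, const, proto, tau)
  sb <- Mod(blood_signal(state, const, proto, tau))
  n <- length(st)
  dbv <- rep_len(state$dbv, n)
  s0 <- rep_len(state$s0, n)
  s0 * dbv * sb + (1 - dbv) * st
}
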