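# Multi-delay pcASL quantification with the general kinetic model. The
# labeled-blood difference signal for a plug-flow bolus of duration LD
# arriving at the arterial transit time ATT is zero before arrival, rises
# during bolus delivery, and decays with the tissue T1 afterwards. Perfusion
# f is internal in mL g^-1 s^-1; CBF is reported in mL/100 g/min (x 6000).

# Unit-M0 kinetic model; f in mL/g/s, t = label_duration + pld (time since
# labeling onset). Vectorized over f, att and t by recycling.
.asl_model <- function(f, att, proto, t) {
  ld <- proto$label_duration
  n <- max(length(f), length(att), length(t))
  f <- rep_len(f, n); att <- rep_len(att, n); t <- rep_len(t, n)
  scale <- 2 * proto$alpha * (1 / proto$lam) * f * proto$t1t *
    exp(-att / proto$t1b)
  dm <- numeric(n)
  during <- t >= att & t < att + ld
  after <- t >= att + ld
  dm[during] <- scale[during] * (1 - exp(-(t[during] - att[during]) /
                                           proto$t1t))
  dm[after] <- scale[after] * (1 - exp(-ld / proto$t1t)) *
    exp(-(t[after] - att[after] - ld) / proto$t1t)
  dm
}

#' Perfusion state of one voxel
#'
#' @param cbf perfusion in mL/100 g/min (>= 0).
#' @param att arterial transit time in seconds (>= 0).
#' @param m0 equilibrium magnetization, arbitrary units.
#' @return object of class \code{perfusion_state}.
#' @export
perfusion_state <- function(cbf = 60, att = 1.3, m0 = 1) {
  stopifnot(all(cbf >= 0), all(att >= 0))
  structure(list(cbf = cbf, att = att, m0 = m0), class = "perfusion_state")
}

#' pcASL difference signal at one post-labeling delay
#'
#' General kinetic model for the label/control difference at time
#' \code{t = label_duration + pld} after labeling onset:
#' zero for \code{t < att}; during bolus delivery
#' \deqn{\Delta M = 2\alpha (M_0/\lambda) f T_{1t} e^{-ATT/T_{1b}}
#'   (1 - e^{-(t - ATT)/T_{1t}})}
#' and after the bolus the delivered magnetization decays with
#' \eqn{e^{-(t - ATT - LD)/T_{1t}}}. Continuous in \code{t} at both branch
#' boundaries, and linear in both perfusion and \code{m0}.
#'
#' @param state \code{\link{perfusion_state}} (cbf in mL/100 g/min).
#' @param proto \code{\link{asl_protocol}}.
#' @param pld post-labeling delay(s) in seconds, >= 0; vectorized.
#' @return difference signal (same units as m0).
#' @export
asl_signal <- function(state, proto = asl_protocol(), pld) {
  if (any(pld < 0)) stop("pld must be non-negative")
  f <- state$cbf / 6000   # mL/100g/min -> mL/g/s
  state$m0 * .asl_model(f, state$att, proto, proto$label_duration + pld)
}

#' Fit CBF and ATT from a multi-delay difference series
#'
#' Nonlinear least squares over (f, ATT). Because the kinetic model is linear
#' in f, perfusion is profiled out in closed form at each candidate ATT
#' (non-negativity clamped) and the fit reduces to a 1-D search over ATT,
#' done on a deterministic coarse grid refined with \code{stats::optimize}.
#' ATT search starts from the conventional initialization of 1.3 s in the
#' sense that the grid covers [0, label_duration + max(pld)].
#'
#' @param series numeric vector of difference-signal values, one per protocol
#'   PLD (ascending order).
#' @param m0 calibration (equilibrium magnetization) value, > 0.
#' @param proto \code{\link{asl_protocol}}.
#' @return \code{perfusion_state} with an extra \code{valid} flag and
#'   \code{rss}; invalid (NA estimates) for non-finite input or m0 <= 0.
#' @export
fit_cbf_att <- function(series, m0, proto = asl_protocol()) {
  if (length(series) != length(proto$plds)) {
    stop("series length does not match the protocol PLD count")
  }
  if (length(proto$plds) < 2) stop("need at least 2 PLDs")
  bad <- structure(list(cbf = NA_real_, att = NA_real_, m0 = m0,
                        valid = FALSE, rss = NA_real_),
                   class = "perfusion_state")
  if (!all(is.finite(series)) || !is.finite(m0) || m0 <= 0) return(bad)
  t <- proto$label_duration + proto$plds

  profile_rss <- function(att) {
    m <- m0 * .asl_model(1, att, proto, t)   # model at unit f
    mm <- sum(m * m)
    f <- if (mm > 0) max(0, sum(series * m) / mm) else 0
    c(rss = sum((series - f * m)^2), f = f)
  }
  att_max <- max(t)
  grid <- seq(0, att_max, by = 0.05)
  rss_grid <- vapply(grid, function(a) profile_rss(a)["rss"], numeric(1))
  a0 <- grid[which.min(rss_grid)]
  lo <- max(0, a0 - 0.06); hi <- min(att_max, a0 + 0.06)
  opt <- stats::optimize(function(a) profile_rss(a)["rss"], c(lo, hi),
                         tol = 1e-10)
  att <- opt$minimum
  pr <- profile_rss(att)
  if (pr["f"] == 0) att <- 0   # no signal: ATT unidentifiable, report 0
  structure(list(cbf = unname(pr["f"]) * 6000, att = att, m0 = m0,
                 valid = TRUE, rss = unname(pr["rss"])),
            class = "perfusion_state")
}

#' Smooth an ASL series before fitting
#'
#' Applies \code{\link{smooth_volume}} with the ASL default kernel
#' (sigma = 1.5 mm) to each volume of a 4-D series (or to a single 3-D
#' volume).
#'
#' @param volumes 3-D or 4-D numeric array.
#' @param sigma_mm kernel SD in mm.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @return array of the same shape.
#' @export
preprocess_asl <- function(volumes, sigma_mm = 1.5,
                           voxel_size_mm = c(3, 3, 3)) {
  d <- dim(volumes)
  if (length(d) == 3) return(smooth_volume(volumes, sigma_mm, voxel_size_mm))
  if (length(d) != 4) stop("expected a 3-D or 4-D array")
  for (k in seq_len(d[4])) {
    volumes[, , , k] <- smooth_volume(volumes[, , , k], sigma_mm,
                                      voxel_size_mm)
  }
  volumes
}

#' Fit CBF and ATT over a masked volume
#'
#' Runs \code{\link{fit_cbf_att}} on every masked voxel of a 4-D
#' difference-signal series with a voxelwise M0 calibration volume.
#' Identical (series, m0) pairs are fitted once and reused.
#'
#' @param dm_4d 4-D array (x, y, z, pld) of difference signals, ascending
#'   PLD order.
#' @param m0_vol 3-D array of M0 values.
#' @param mask 3-D logical array.
#' @param proto \code{\link{asl_protocol}}.
#' @param dedupe fit unique series only.
#' @return list of 3-D arrays \code{cbf} (mL/100 g/min), \code{att} (s) and
#'   logical \code{valid}; NA outside the mask or where invalid.
#' @export
fit_asl_volume <- function(dm_4d, m0_vol, mask, proto = asl_protocol(),
                           dedupe = TRUE) {
  d <- dim(dm_4d)
  if (length(d) != 4) stop("dm_4d must be 4-D (x, y, z, pld)")
  if (d[4] != length(proto$plds)) stop("PLD count mismatch with protocol")
  mask <- array(as.logical(mask), d[1:3])
  cbf <- att <- array(NA_real_, d[1:3])
  valid <- array(FALSE, d[1:3])
  vox <- which(mask)
  if (!length(vox)) return(list(cbf = cbf, att = att, valid = valid))
  sig <- cbind(matrix(dm_4d, prod(d[1:3]), d[4])[vox, , drop = FALSE],
               m0_vol[vox])
  if (dedupe) {
    key <- apply(sig, 1, paste, collapse = "\r")
    first <- !duplicated(key)
    uidx <- match(key, key[first])
    usig <- sig[first, , drop = FALSE]
  } else {
    uidx <- seq_len(nrow(sig))
    usig <- sig
  }
  fits <- lapply(seq_len(nrow(usig)), function(i) {
    fit_cbf_att(usig[i, seq_len(d[4])], usig[i, d[4] + 1L], proto)
  })
  cbf[vox] <- vapply(fits, `[[`, numeric(1), "cbf")[uidx]
  att[vox] <- vapply(fits, `[[`, numeric(1), "att")[uidx]
  valid[vox] <- vapply(fits, `[[`, logical(1), "valid")[uidx]
  list(cbf = cbf, att = att, valid = valid)
}
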