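# Voxelwise maximum-a-posteriori (MAP) estimation of (S0, R2', DBV) from an
# ASE tau-series under the two-compartment qBOLD forward model, with
# independent Gaussian priors on R2' and DBV on the natural scale and a flat
# prior on S0. The point estimates match a Gaussian variational posterior's
# means; a Laplace covariance supplies the uncertainty. The per-voxel noise
# SD is re-estimated from residuals in a small number of outer iterations.

# Unit-amplitude forward model used inside the optimizer. No range checks:
# trial (r2p, dbv) pairs may imply OEF > 1 and the empirical R2b quadratic is
# simply extrapolated there; validity is enforced by priors and by the
# physiological exclusion stage, not by the optimizer.
.qbold_model_unit <- function(r2p, dbv, taus, te, b0, const) {
  dbv <- max(dbv, 1e-10)   # logistic underflow guard: keep delta_omega finite
  dw <- r2p / dbv
  oef <- dw / ((4 * pi / 3) * const$gamma * b0 * const$dchi0 * const$hct)
  r2b_v <- 16.4 * const$hct + 4.5 + (165.2 * const$hct + 55.7) * oef^2
  u <- dw * taus
  short <- u < 1.76
  st <- exp(-const$r2t * te) *
    exp(ifelse(short, -0.3 * dbv * u^2, dbv - dbv * u))
  sb <- exp(-r2b_v * te) * Mod(fresnel_ratio(u))
  dbv * sb + (1 - dbv) * st
}

.softplus <- function(a) ifelse(a > 30, a, log1p(exp(a)))
.softplus_inv <- function(x) ifelse(x > 30, x, log(expm1(x)))

#' Fit the qBOLD model in one voxel
#'
#' Maximizes the Gaussian-likelihood posterior of the two-compartment ASE
#' model in (S0, R2', DBV). S0 carries a flat prior and is profiled out in
#' closed form; R2' and DBV carry independent Gaussian priors
#' (\code{\link{prior_spec}}) applied on the natural scale while the
#' optimizer works on softplus/logit-transformed coordinates to keep both
#' positive (and DBV < 1). The noise SD is re-estimated from the residuals
#' after each inner optimization, up to \code{n_outer} times or until the
#' objective changes by less than \code{tol}. Deterministic: initialization
#' is at the prior means with S0 taken from the tau = 0 sample.
#'
#' @param signal numeric vector of ASE magnitudes, one per protocol tau.
#' @param proto \code{\link{ase_protocol}}; must include tau = 0 and at least
#'   4 tau points.
#' @param const \code{\link{tissue_constants}}.
#' @param priors \code{\link{prior_spec}}.
#' @param n_outer maximum noise-reestimation iterations.
#' @param tol absolute tolerance on the objective for outer convergence.
#' @param sigma optional known noise SD; if supplied it is held fixed
#'   (no re-estimation from residuals). As \code{sigma} grows on a fixed
#'   dataset the posterior estimates shrink to the prior means.
#' @return object of class \code{voxel_posterior}: list with \code{mean}
#'   (named s0, r2p, dbv), \code{sd} (Laplace posterior SDs, NA if the
#'   Hessian is not positive definite), \code{sigma} (noise SD),
#'   \code{objective}, \code{converged}, \code{valid}.
#' @export
fit_voxel <- function(signal, proto = ase_protocol(),
                      const = tissue_constants(), priors = prior_spec(),
                      n_outer = 5L, tol = 1e-8, sigma = NULL) {
  taus <- proto$taus
  if (length(taus) < 4 || !any(taus == 0)) {
    stop("protocol must provide at least 4 tau points including tau = 0")
  }
  if (length(signal) != length(taus)) {
    stop("signal length does not match the protocol tau count")
  }
  invalid <- structure(
    list(mean = c(s0 = NA_real_, r2p = NA_real_, dbv = NA_real_),
         sd = c(s0 = NA_real_, r2p = NA_real_, dbv = NA_real_),
         sigma = NA_real_, objective = NA_real_,
         converged = FALSE, valid = FALSE),
    class = "voxel_posterior")
  if (!all(is.finite(signal)) || all(signal == 0)) return(invalid)

  te <- proto$te; b0 <- proto$b0
  n <- length(signal)

  profile_fit <- function(r2p, dbv) {
    m <- .qbold_model_unit(r2p, dbv, taus, te, b0, const)
    mm <- sum(m * m)
    s0 <- sum(signal * m) / mm
    rss <- sum((signal - s0 * m)^2)
    list(s0 = s0, rss = rss)
  }
  penalty <- function(r2p, dbv) {
    (r2p - priors$mu0_r2p)^2 / (2 * priors$sigma0_r2p^2) +
      (dbv - priors$mu0_dbv)^2 / (2 * priors$sigma0_dbv^2)
  }
  objective <- function(theta, sigma2) {
    r2p <- .softplus(theta[1]); dbv <- stats::plogis(theta[2])
    pf <- profile_fit(r2p, dbv)
    pf$rss / (2 * sigma2) + penalty(r2p, dbv)
  }

  floor2 <- (1e-6 * max(abs(signal)))^2

  # Deterministic starting points: the prior means, and a log-linear
  # ("streamlined") estimate -- R2' from the slope of log S over the long-tau
  # points and DBV from the offset between the spin-echo sample and the
  # extrapolated long-tau intercept. The qBOLD posterior is banana-shaped and
  # a single start can stall in a shallow local minimum.
  starts <- list(c(priors$mu0_r2p, priors$mu0_dbv))
  long <- taus >= 0.016
  if (sum(long) >= 2 && all(signal > 0)) {
    co <- stats::coef(stats::lm(log(signal[long]) ~ taus[long]))
    r2p0 <- max(0.1, -co[[2]])
    dbv0 <- min(0.3, max(0.005, co[[1]] - log(signal[taus == 0][1])))
    starts[[2]] <- c(r2p0, dbv0)
  }

  run_from <- function(start) {
    theta <- c(.softplus_inv(start[1]), stats::qlogis(start[2]))
    # Stage 0: unpenalized least squares. The noise SD must come from the
    # residuals of a best fit, not from the residuals at the starting guess
    # (which would conflate model mismatch with noise and can trap the
    # alternating scheme at a spurious fixed point).
    nls_obj <- function(th) {
      profile_fit(.softplus(th[1]), stats::plogis(th[2]))$rss
    }
    opt0 <- stats::optim(theta, nls_obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 500))
    theta <- opt0$par
    fixed_sigma <- !is.null(sigma)
    sigma2 <- if (fixed_sigma) sigma^2 else max(opt0$value / n, floor2)
    obj_prev <- Inf
    converged <- FALSE
    for (it in seq_len(if (fixed_sigma) 2L else n_outer)) {
      opt <- stats::optim(theta, objective, sigma2 = sigma2,
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 500))
      theta <- opt$par
      r2p <- .softplus(theta[1]); dbv <- stats::plogis(theta[2])
      pf <- profile_fit(r2p, dbv)
      sigma2_new <- if (fixed_sigma) sigma2 else max(pf$rss / n, floor2)
      if (abs(opt$value - obj_prev) < tol && it > 1) {
        converged <- TRUE
        sigma2 <- sigma2_new
        break
      }
      obj_prev <- opt$value
      sigma2 <- sigma2_new
    }
    r2p <- .softplus(theta[1]); dbv <- stats::plogis(theta[2])
    pf <- profile_fit(r2p, dbv)
    # selection criterion across starts: negative log posterior (sigma
    # profiled when it is estimated, plugged in when it is known)
    crit <- if (fixed_sigma) {
      pf$rss / (2 * sigma2) + penalty(r2p, dbv)
    } else {
      n / 2 * log(max(pf$rss / n, floor2)) + penalty(r2p, dbv)
    }
    list(r2p = r2p, dbv = dbv, pf = pf, sigma2 = sigma2,
         converged = converged, crit = crit)
  }
  cands <- lapply(starts, run_from)
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "crit"))]]
  r2p <- best$r2p; dbv <- best$dbv; pf <- best$pf
  sigma2 <- best$sigma2; converged <- best$converged

  # Laplace covariance on the natural (r2p, dbv) scale at fixed noise SD
  Jnat <- function(p) {
    f <- profile_fit(p[1], p[2])
    f$rss / (2 * sigma2) + penalty(p[1], p[2])
  }
  p0 <- c(r2p, dbv)
  hstep <- pmax(abs(p0) * 1e-4, 1e-7)
  H <- matrix(NA_real_, 2, 2)
  f0 <- Jnat(p0)
  for (i in 1:2) for (j in i:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    if (i == j) {
      H[i, i] <- (Jnat(p0 + ei) - 2 * f0 + Jnat(p0 - ei)) / hstep[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (Jnat(p0 + ei + ej) - Jnat(p0 + ei - ej) -
           Jnat(p0 - ei + ej) + Jnat(p0 - ei - ej)) /
        (4 * hstep[i] * hstep[j])
    }
  }
  sds <- c(s0 = sqrt(sigma2 / sum(.qbold_model_unit(r2p, dbv, taus, te, b0,
                                                    const)^2)),
           r2p = NA_real_, dbv = NA_real_)
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(-1, -1))
  if (all(ev > 0)) {
    cov <- solve(H)
    sds[c("r2p", "dbv")] <- sqrt(diag(cov))
  }

  structure(
    list(mean = c(s0 = pf$s0, r2p = r2p, dbv = dbv),
         sd = sds, sigma = sqrt(sigma2),
         objective = pf$rss / (2 * sigma2) + penalty(r2p, dbv),
         converged = converged || n_outer == 1L, valid = TRUE),
    class = "voxel_posterior")
}

#' Construct a parameter-map container
#' @noRd
.parameter_maps <- function(shape, voxel_size_mm) {
  structure(
    list(r2p = array(NA_real_, shape), dbv = array(NA_real_, shape),
         s0 = array(NA_real_, shape), oef = NULL,
         valid = array(FALSE, shape),
         meta = list(shape = shape, voxel_size_mm = voxel_size_mm)),
    class = "parameter_maps")
}

#' Fit the qBOLD model over a masked volume
#'
#' Optionally smooths each tau volume with a Gaussian kernel (default
#' sigma = 4 mm, matching the human ASE protocol; set
#' \code{smooth_sigma_mm = 0} for noise-free synthetic data), then runs
#' \code{\link{fit_voxel}} on every voxel in the mask. Voxels outside the
#' mask, and voxels whose fit fails, are invalid and carry NA. Identical
#' tau-series are fitted once and the result reused
#' (\code{fit_voxel} is deterministic, so this is exact).
#'
#' @param ase_4d 4-D array (x, y, z, tau) of ASE magnitudes ordered by
#'   ascending tau.
#' @param mask 3-D logical array (or 0/1) selecting voxels to fit.
#' @param proto,const,priors model specification as in
#'   \code{\link{fit_voxel}}.
#' @param smooth_sigma_mm Gaussian kernel SD in mm applied to each tau volume
#'   before fitting; 0 disables.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @param dedupe fit unique tau-series only (exact memoization).
#' @param verbose log per-slab progress.
#' @return object of class \code{parameter_maps} with fields \code{r2p},
#'   \code{dbv}, \code{s0} (3-D arrays, NA where invalid), \code{valid}
#'   (logical array), and \code{meta}.
#' @export
fit_volume <- function(ase_4d, mask, proto = ase_protocol(),
                       const = tissue_constants(), priors = prior_spec(),
                       smooth_sigma_mm = 4, voxel_size_mm = c(3, 3, 3),
                       dedupe = TRUE, verbose = FALSE) {
  d <- dim(ase_4d)
  if (length(d) != 4) stop("ase_4d must be a 4-D array (x, y, z, tau)")
  if (d[4] != length(proto$taus)) {
    stop("tau count mismatch: data has ", d[4], " volumes but protocol has ",
         length(proto$taus), " tau values")
  }
  mask <- array(as.logical(mask), d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match volume")

  if (smooth_sigma_mm > 0) {
    for (k in seq_len(d[4])) {
      ase_4d[, , , k] <- smooth_volume(ase_4d[, , , k], smooth_sigma_mm,
                                       voxel_size_mm)
    }
  }

  maps <- .parameter_maps(d[1:3], voxel_size_mm)
  vox <- which(mask)
  if (length(vox) == 0) return(maps)
  nvox_grid <- prod(d[1:3])
  sig <- matrix(ase_4d, nrow = nvox_grid, ncol = d[4])[vox, , drop = FALSE]

  if (dedupe) {
    key <- apply(sig, 1, paste, collapse = "\r")
    first <- !duplicated(key)
    uidx <- match(key, key[first])
    usig <- sig[first, , drop = FALSE]
  } else {
    uidx <- seq_len(nrow(sig))
    usig <- sig
  }
  nfit <- nrow(usig)
  fits <- vector("list", nfit)
  slab <- max(1L, nfit %/% 10L)
  for (i in seq_len(nfit)) {
    fits[[i]] <- fit_voxel(usig[i, ], proto, const, priors)
    if (verbose && i %% slab == 0) {
      message(sprintf("fit_volume: %d / %d unique voxels", i, nfit))
    }
  }
  means <- t(vapply(fits, function(f) f$mean, numeric(3)))
  valid <- vapply(fits, function(f) f$valid, logical(1))
  maps$s0[vox] <- means[uidx, "s0"]
  maps$r2p[vox] <- means[uidx, "r2p"]
  maps$dbv[vox] <- means[uidx, "dbv"]
  maps$valid[vox] <- valid[uidx]
  maps
}

#' Compute the OEF map from fitted R2' and DBV
#'
#' \code{oef = 3 r2p / (4 pi gamma b0 dchi0 hct dbv)} per voxel. Voxels with
#' DBV = 0 (or invalid inputs) are marked invalid rather than raising.
#'
#' @param maps \code{parameter_maps} from \code{\link{fit_volume}}.
#' @param const \code{\link{tissue_constants}}.
#' @param b0 field strength in tesla.
#' @return the input \code{parameter_maps} with \code{oef} filled and
#'   \code{valid} updated.
#' @export
oef_map <- function(maps, const = tissue_constants(), b0 = 3) {
  stopifnot(inherits(maps, "parameter_maps"))
  oef <- array(NA_real_, maps$meta$shape)
  ok <- maps$valid & is.finite(maps$r2p) & is.finite(maps$dbv) & maps$dbv > 0
  oef[ok] <- oef_from_r2p_dbv(maps$r2p[ok], maps$dbv[ok], const, b0)
  maps$oef <- oef
  maps$valid <- ok & is.finite(oef)
  maps
}

#' Exclude voxels with unphysiological estimates
#'
#' Invalidates voxels with OEF strictly greater than 1 (100\%), R2' strictly
#' greater than \code{r2p_max}, or non-finite estimates; equality at a
#' threshold is retained. Excluded voxels become NA in all maps.
#'
#' @param maps \code{parameter_maps} with \code{oef} filled
#'   (\code{\link{oef_map}}).
#' @param oef_max OEF exclusion threshold as a fraction (default 1).
#' @param r2p_max R2' exclusion threshold in s^-1 (default 20).
#' @return list with \code{maps} (updated) and \code{report}: percentages of
#'   previously valid voxels excluded by the OEF rule, the R2' rule, and in
#'   total.
#' @export
physiological_exclusion <- function(maps, oef_max = 1, r2p_max = 20) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (is.null(maps$oef)) stop("run oef_map() before physiological_exclusion()")
  was_valid <- maps$valid
  n0 <- sum(was_valid)
  bad_oef <- was_valid & (!is.finite(maps$oef) | maps$oef > oef_max)
  bad_r2p <- was_valid & (!is.finite(maps$r2p) | maps$r2p > r2p_max)
  bad <- bad_oef | bad_r2p
  maps$valid <- was_valid & !bad
  for (f in c("r2p", "dbv", "s0", "oef")) maps[[f]][bad] <- NA_real_
  pct <- function(x) if (n0 == 0) 0 else 100 * sum(x) / n0
  list(maps = maps,
       report = list(pct_excluded_oef = pct(bad_oef),
                     pct_excluded_r2p = pct(bad_r2p),
                     pct_excluded_total = pct(bad),
                     n_valid_before = n0, n_valid_after = sum(maps$valid)))
}

#' Group-average map with a minimum-support rule
#'
#' Voxelwise mean over subjects' valid values, reported only where at least
#' \code{ceiling(N/2)} subjects (half the population, rounding up) are valid;
#' elsewhere NA. The support map carries the per-voxel valid count.
#'
#' @param subject_maps list of \code{parameter_maps} on a shared grid.
#' @param field which map to average ("oef", "r2p", "dbv", "s0").
#' @return list with \code{mean} (3-D array), \code{support} (integer array),
#'   \code{min_support} used.
#' @export
group_average_map <- function(subject_maps, field = "oef") {
  stopifnot(length(subject_maps) >= 1)
  shapes <- lapply(subject_maps, function(m) m$meta$shape)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    stop("subject maps are not on a shared grid")
  }
  N <- length(subject_maps)
  min_support <- ceiling(N / 2)
  vols <- lapply(subject_maps, function(m) {
    v <- m[[field]]
    v[!m$valid] <- NA_real_
    v
  })
  stack <- array(unlist(vols), dim = c(shapes[[1]], N))
  support <- apply(!is.na(stack), 1:3, sum)
  mean_map <- apply(stack, 1:3, function(x) mean(x, na.rm = TRUE))
  mean_map[support < min_support] <- NA_real_
  mean_map[is.nan(mean_map)] <- NA_real_
  list(mean = mean_map, support = support, min_support = min_support)
}
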