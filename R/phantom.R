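# Digital phantom: aligned ASE and ASL datasets for two physiological
# conditions (pre/post vasodilation) with known ground truth. ROIs are laid
# out as disjoint cubic blocks on a small grid; per-subject ROI parameter
# values are drawn from Gaussians with the published per-ROI means and
# between-subject SDs. R2' truth is always derived from (OEF, DBV) through
# the dephasing relation, so the forward model and the truth are consistent
# by construction.

#' Phantom specification
#'
#' @param roi_table data.frame as \code{\link{reference_roi_table}}: one row
#'   per (roi, condition) with \code{cbf_mean/sd}, \code{oef_mean/sd} (%),
#'   \code{dbv_mean/sd} (%).
#' @param grid_shape 3-D grid dimensions.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @param n_subjects number of simulated subjects.
#' @param snr_ase amplitude SNR of the ASE data at tau = 0 (Inf = noiseless).
#' @param snr_asl amplitude SNR of the ASL data relative to M0.
#' @param seed RNG seed (mandatory).
#' @param sd_scale multiplier on all between-subject SDs (0 gives every
#'   subject the table means exactly).
#' @param jitter_sd within-ROI spatial jitter SD as a fraction of the ROI
#'   value (default 0: truth constant within an ROI).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(roi_table = reference_roi_table(),
                         grid_shape = c(24, 24, 24),
                         voxel_size_mm = c(3, 3, 3),
                         n_subjects = 8L, snr_ase = Inf, snr_asl = Inf,
                         seed, sd_scale = 1, jitter_sd = 0) {
  if (missing(seed) || is.null(seed)) stop("phantom_spec requires a seed")
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            n_subjects >= 1, snr_ase > 0, snr_asl > 0,
            sd_scale >= 0, jitter_sd >= 0,
            all(c("roi", "condition", "cbf_mean", "oef_mean", "dbv_mean")
                %in% names(roi_table)))
  rois <- unique(roi_table$roi)
  structure(list(roi_table = roi_table, rois = rois,
                 labels = stats::setNames(seq_along(rois), rois),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_subjects = as.integer(n_subjects),
                 snr_ase = snr_ase, snr_asl = snr_asl,
                 seed = as.integer(seed), sd_scale = sd_scale,
                 jitter_sd = jitter_sd),
            class = "phantom_spec")
}

#' Default phantom specification from the published reference table
#'
#' Nine-ROI phantom parameterized by the published pre/post means and
#' between-subject SDs, eight subjects, noiseless by default.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to \code{\link{phantom_spec}}.
#' @return \code{phantom_spec}.
#' @export
#' @examples
#' spec <- default_table_spec(seed = 1)
#' subset(spec$roi_table, roi == "pCG" & condition == "pre")$cbf_mean  # 76.3
default_table_spec <- function(seed = 1L, ...) {
  phantom_spec(roi_table = reference_roi_table(), seed = seed, ...)
}

# block layout: ROIs arranged on a 3 x 3 x-y lattice of cubes in a central
# z slab, separated by background
.layout_atlas <- function(spec) {
  g <- spec$grid_shape
  n_roi <- length(spec$rois)
  ncell <- ceiling(sqrt(n_roi))
  cell <- floor(min(g[1], g[2]) / ncell)
  side <- max(2L, cell - 2L)
  z0 <- max(1L, floor((g[3] - side) / 2) + 1L)
  zr <- z0:min(g[3], z0 + side - 1L)
  atlas <- array(0L, g)
  for (k in seq_len(n_roi)) {
    ix <- (k - 1) %% ncell
    iy <- (k - 1) %/% ncell
    xr <- (ix * cell + 1L):(ix * cell + side)
    yr <- (iy * cell + 1L):(iy * cell + side)
    if (any(atlas[xr, yr, zr] != 0L)) stop("ROI blocks overlap")
    atlas[xr, yr, zr] <- k
  }
  atlas
}

#' Build the phantom ground truth
#'
#' Lays out the ROIs as disjoint blocks, then draws per-subject, per-ROI,
#' per-condition parameter values from Gaussians with the spec's means and
#' (scaled) SDs, truncated to physiological ranges. OEF and DBV are the
#' generative parameters; R2' is derived as \code{dbv * delta_omega(oef)} so
#' the truth is internally consistent. ATT is fixed at 1.3 s and S0 = M0 = 1.
#'
#' @param spec \code{\link{phantom_spec}}.
#' @param const \code{\link{tissue_constants}} for the R2' derivation.
#' @param b0 field strength in tesla.
#' @return object of class \code{phantom_truth}: \code{atlas} (integer
#'   volume, 0 = background), \code{roi_truth} (data.frame of per-subject
#'   ROI scalars, fractions for oef/dbv), and the \code{spec}.
#' @export
build_phantom <- function(spec, const = tissue_constants(), b0 = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  atlas <- .layout_atlas(spec)
  set.seed(spec$seed)
  tab <- spec$roi_table
  rows <- expand.grid(subject = seq_len(spec$n_subjects),
                      condition = c("pre", "post"),
                      roi = spec$rois, stringsAsFactors = FALSE)
  m <- match(paste(rows$roi, rows$condition),
             paste(tab$roi, tab$condition))
  if (anyNA(m)) stop("roi_table is missing a (roi, condition) combination")
  sc <- spec$sd_scale
  n <- nrow(rows)
  draw <- function(mu, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mu, sc * sd), lo), hi)
  }
  oef <- draw(tab$oef_mean[m] / 100, tab$oef_sd[m] / 100, 0.02, 0.95)
  dbv <- draw(tab$dbv_mean[m] / 100, tab$dbv_sd[m] / 100, 0.005, 0.40)
  cbf <- draw(tab$cbf_mean[m], tab$cbf_sd[m], 5, Inf)
  truth <- data.frame(rows,
                      label = unname(spec$labels[rows$roi]),
                      oef = oef, dbv = dbv,
                      r2p = dbv * delta_omega(oef, const, b0),
                      cbf = cbf, att = 1.3, s0 = 1, m0 = 1)
  structure(list(atlas = atlas, roi_truth = truth, spec = spec,
                 const = const, b0 = b0),
            class = "phantom_truth")
}

#' Paint a subject/condition truth map onto the phantom grid
#'
#' @param truth \code{\link{build_phantom}} result.
#' @param subject subject index.
#' @param condition "pre" or "post".
#' @param jitter_seed seed for within-ROI jitter (only used if the spec's
#'   \code{jitter_sd > 0}).
#' @return list of 3-D arrays \code{oef}, \code{dbv}, \code{r2p}, \code{cbf},
#'   \code{att}, \code{s0}, \code{m0} (NA in the background).
#' @export
truth_maps <- function(truth, subject, condition, jitter_seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  rt <- truth$roi_truth
  sel <- rt$subject == subject & rt$condition == condition
  if (!any(sel)) stop("unknown subject/condition")
  rt <- rt[sel, ]
  atlas <- truth$atlas
  out <- list()
  for (f in c("oef", "dbv", "r2p", "cbf", "att", "s0", "m0")) {
    v <- array(NA_real_, dim(atlas))
    v[atlas > 0] <- rt[[f]][match(atlas[atlas > 0], rt$label)]
    out[[f]] <- v
  }
  js <- truth$spec$jitter_sd
  if (js > 0) {
    if (!is.null(jitter_seed)) set.seed(jitter_seed)
    inroi <- which(atlas > 0)
    for (f in c("oef", "dbv", "cbf")) {
      out[[f]][inroi] <- pmax(out[[f]][inroi] *
                                (1 + stats::rnorm(length(inroi), 0, js)),
                              .Machine$double.eps)
    }
    out$r2p[inroi] <- out$dbv[inroi] *
      delta_omega(pmin(out$oef[inroi], 1), truth$const, truth$b0)
  }
  out
}

#' Simulate an ASE study from the phantom
#'
#' Evaluates the two-compartment forward model voxelwise at every tau of the
#' protocol for each subject and condition, and adds independent Gaussian
#' thermal noise with SD equal to the mean in-ROI tau = 0 signal divided by
#' \code{snr} (\code{snr = Inf}: noise-free). Noise realizations differ
#' across subjects/conditions but are reproducible under \code{seed}.
#'
#' @param truth \code{\link{build_phantom}} result.
#' @param proto \code{\link{ase_protocol}}.
#' @param snr amplitude SNR at tau = 0 (defaults to the spec's
#'   \code{snr_ase}).
#' @param seed RNG seed (defaults to the spec's seed + 1).
#' @return nested list \code{data[[subject]][[condition]]}, each a 4-D array
#'   (x, y, z, tau); attribute-free, background voxels carry 0 signal plus
#'   noise. Also returns \code{noise_sd}.
#' @export
simulate_ase_study <- function(truth, proto = ase_protocol(),
                               snr = truth$spec$snr_ase,
                               seed = truth$spec$seed + 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(seed)
  g <- dim(truth$atlas)
  inroi <- which(truth$atlas > 0)
  subjects <- seq_len(truth$spec$n_subjects)
  noise_sd <- NA_real_
  data <- lapply(subjects, function(s) {
    per_cond <- lapply(c(pre = "pre", post = "post"), function(cond) {
      tm <- truth_maps(truth, s, cond,
                       jitter_seed = truth$spec$seed + 1000L * s +
                         ifelse(cond == "pre", 1L, 2L))
      st <- voxel_state(s0 = tm$s0[inroi], oef = tm$oef[inroi],
                        dbv = tm$dbv[inroi])
      vol <- array(0, c(g, length(proto$taus)))
      for (k in seq_along(proto$taus)) {
        sl <- array(0, g)
        sl[inroi] <- total_signal(st, truth$const, proto, proto$taus[k])
        vol[, , , k] <- sl
      }
      if (is.finite(snr)) {
        sd0 <- mean(vol[, , , which(proto$taus == 0)][inroi]) / snr
        noise_sd <<- sd0
        vol <- vol + array(stats::rnorm(length(vol), 0, sd0), dim(vol))
      } else noise_sd <<- 0
      vol
    })
    per_cond
  })
  list(data = data, noise_sd = noise_sd, proto = proto)
}

#' Simulate an ASL study from the phantom
#'
#' Kinetic-model difference signals at each PLD plus an M0 calibration
#' volume per subject and condition. Gaussian noise is added to the
#' difference series with SD equal to the mean in-ROI peak difference signal
#' divided by \code{snr} (SNR defined on the perfusion-weighted signal, as
#' is conventional for ASL difference images).
#'
#' @param truth \code{\link{build_phantom}} result.
#' @param proto \code{\link{asl_protocol}}.
#' @param snr amplitude SNR relative to M0 (defaults to the spec's
#'   \code{snr_asl}).
#' @param seed RNG seed (defaults to the spec's seed + 2).
#' @return list \code{data[[subject]][[condition]]} with elements \code{dm}
#'   (4-D, x,y,z,pld) and \code{m0} (3-D), plus \code{noise_sd}.
#' @export
simulate_asl_study <- function(truth, proto = asl_protocol(),
                               snr = truth$spec$snr_asl,
                               seed = truth$spec$seed + 2L) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(seed)
  g <- dim(truth$atlas)
  inroi <- which(truth$atlas > 0)
  subjects <- seq_len(truth$spec$n_subjects)
  noise_sd <- NA_real_
  data <- lapply(subjects, function(s) {
    lapply(c(pre = "pre", post = "post"), function(cond) {
      tm <- truth_maps(truth, s, cond,
                       jitter_seed = truth$spec$seed + 2000L * s +
                         ifelse(cond == "pre", 1L, 2L))
      st <- perfusion_state(cbf = tm$cbf[inroi], att = tm$att[inroi],
                            m0 = tm$m0[inroi])
      dm <- array(0, c(g, length(proto$plds)))
      for (k in seq_along(proto$plds)) {
        sl <- array(0, g)
        sl[inroi] <- asl_signal(st, proto, proto$plds[k])
        dm[, , , k] <- sl
      }
      m0 <- array(0, g)
      m0[inroi] <- tm$m0[inroi]
      if (is.finite(snr)) {
        dmm <- matrix(dm, prod(g), length(proto$plds))[inroi, , drop = FALSE]
        sd0 <- mean(apply(abs(dmm), 1, max)) / snr
        noise_sd <<- sd0
        dm <- dm + array(stats::rnorm(length(dm), 0, sd0), dim(dm))
      } else noise_sd <<- 0
      list(dm = dm, m0 = m0)
    })
  })
  list(data = data, noise_sd = noise_sd, proto = proto)
}
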