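# Acquisition protocols and physical-constant containers. All values are SI
# internally (seconds, tesla, fractions); percent and milliseconds appear only
# at I/O boundaries.

#' ASE acquisition protocol
#'
#' Container for the asymmetric spin echo (ASE) acquisition constants shared
#' by signal simulation and model fitting: echo time TE, repetition time TR,
#' the ordered spin-echo displacement times tau, and the main field strength.
#'
#' The default scheme is a 3 T protocol with TE = 56 ms and tau running from
#' 16 to 40 ms in 4 ms steps, plus the separately acquired spin-echo point
#' tau = 0.
#'
#' @param te echo time in seconds.
#' @param tr repetition time in seconds.
#' @param taus strictly increasing vector of spin-echo displacement times in
#'   seconds; must include non-negative values only.
#' @param b0 main magnetic field strength in tesla.
#' @return object of class \code{ase_protocol}.
#' @export
#' @examples
#' p <- ase_protocol()
#' p$taus * 1000  # ms
ase_protocol <- function(te = 0.056, tr = 3.0,
                         taus = c(0, seq(0.016, 0.040, by = 0.004)),
                         b0 = 3.0) {
  stopifnot(is.numeric(te), length(te) == 1, te > 0,
            is.numeric(tr), length(tr) == 1, tr > 0,
            is.numeric(b0), length(b0) == 1, b0 > 0,
            is.numeric(taus), length(taus) >= 1, all(taus >= 0),
            all(diff(taus) > 0))
  structure(list(te = te, tr = tr, taus = as.numeric(taus), b0 = b0),
            class = "ase_protocol")
}

#' Tissue and blood physical constants for the qBOLD model
#'
#' @param gamma proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param dchi0 susceptibility difference between fully oxygenated and fully
#'   deoxygenated red blood cells (dimensionless, SI).
#' @param r2t irreversible transverse relaxation rate of bulk tissue, s^-1.
#' @param hct fractional hematocrit, in (0, 1).
#' @return object of class \code{tissue_constants}.
#' @export
tissue_constants <- function(gamma = 2.675e8, dchi0 = 0.264e-6,
                             r2t = 11.5, hct = 0.40) {
  stopifnot(gamma > 0, dchi0 > 0, r2t > 0, hct > 0, hct < 1)
  structure(list(gamma = gamma, dchi0 = dchi0, r2t = r2t, hct = hct),
            class = "tissue_constants")
}

#' Per-voxel physiological state for the qBOLD forward model
#'
#' @param s0 equilibrium signal amplitude (arbitrary units), > 0.
#' @param oef oxygen extraction fraction as a fraction in [0, 1].
#' @param dbv deoxygenated blood volume as a fraction in [0, 1).
#' @return object of class \code{voxel_state}.
#' @export
voxel_state <- function(s0 = 1, oef = 0.4, dbv = 0.036) {
  stopifnot(all(s0 > 0), all(oef >= 0), all(oef <= 1),
            all(dbv >= 0), all(dbv < 1))
  n <- max(length(s0), length(oef), length(dbv))
  structure(list(s0 = rep_len(s0, n), oef = rep_len(oef, n),
                 dbv = rep_len(dbv, n)),
            class = "voxel_state")
}

#' Multi-delay pcASL acquisition and kinetic constants
#'
#' Defaults follow a 3 T multi-delay pseudo-continuous ASL protocol with five
#' post-labeling delays and a 2 s label: T1 of blood 1.65 s, T1 of tissue
#' 1.3 s, partition coefficient 0.9 mL/g, labeling efficiency 0.85.
#'
#' @param plds post-labeling delays in seconds, strictly increasing.
#' @param label_duration label duration in seconds.
#' @param t1b longitudinal relaxation time of arterial blood, seconds.
#' @param t1t longitudinal relaxation time of tissue, seconds.
#' @param lam brain/blood partition coefficient, mL/g.
#' @param alpha labeling efficiency, fraction in (0, 1].
#' @return object of class \code{asl_protocol}.
#' @export
asl_protocol <- function(plds = c(0.9, 1.2, 1.4, 1.8, 2.1),
                         label_duration = 2.0, t1b = 1.65, t1t = 1.3,
                         lam = 0.9, alpha = 0.85) {
  stopifnot(all(plds > 0), all(diff(plds) > 0), label_duration > 0,
            t1b > 0, t1t > 0, lam > 0, alpha > 0, alpha <= 1)
  structure(list(plds = as.numeric(plds), label_duration = label_duration,
                 t1b = t1b, t1t = t1t, lam = lam, alpha = alpha),
            class = "asl_protocol")
}

#' Constants linking OEF and CBF to oxygen metabolism
#'
#' \code{hba}, the oxygenated hemoglobin concentration in the arteriole, is
#' always derived as \code{hbt * ya}; with the defaults (tissue-blood
#' hemoglobin 8.441 umol/mL at hematocrit 0.40, arterial saturation 0.98)
#' this gives 8.272 umol/mL.
#'
#' @param hbt hemoglobin concentration in tissue blood, umol/mL.
#' @param ya arterial oxygen saturation, fraction in (0, 1].
#' @return object of class \code{metabolic_constants} with fields
#'   \code{hbt}, \code{ya}, \code{hba}.
#' @export
metabolic_constants <- function(hbt = 8.441, ya = 0.98) {
  stopifnot(hbt > 0, ya > 0, ya <= 1)
  structure(list(hbt = hbt, ya = ya, hba = hbt * ya),
            class = "metabolic_constants")
}

#' Gaussian priors for the qBOLD MAP fit
#'
#' Prior means 2.6 s^-1 (R2') and 3.6% (DBV) are literature values for healthy
#' gray matter; the prior SDs default to 10^(3/2) s^-1 and 10^(1/2) percent
#' (0.0316 as a fraction).
#'
#' @param mu0_r2p prior mean of R2', s^-1.
#' @param mu0_dbv prior mean of DBV, fraction.
#' @param sigma0_r2p prior SD of R2', s^-1 (> 0).
#' @param sigma0_dbv prior SD of DBV, fraction (> 0).
#' @return object of class \code{prior_spec}.
#' @export
prior_spec <- function(mu0_r2p = 2.6, mu0_dbv = 0.036,
                       sigma0_r2p = 10^(3 / 2), sigma0_dbv = 10^(1 / 2) / 100) {
  stopifnot(sigma0_r2p > 0, sigma0_dbv > 0, mu0_r2p >= 0,
            mu0_dbv >= 0, mu0_dbv < 1)
  structure(list(mu0_r2p = mu0_r2p, mu0_dbv = mu0_dbv,
                 sigma0_r2p = sigma0_r2p, sigma0_dbv = sigma0_dbv),
            class = "prior_spec")
}

#' Default flat configuration of physical constants
#'
#' Returns the full set of tunable constants as a named list, the same keys
#' accepted by \code{\link{read_config}}.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(te_s = 0.056, tr_s = 3.0,
       taus_s = c(0, seq(0.016, 0.040, by = 0.004)),
       b0_T = 3.0, gamma = 2.675e8, dchi0 = 0.264e-6, r2t_s = 11.5,
       hct = 0.40,
       mu0_r2p = 2.6, mu0_dbv = 0.036,
       sigma0_r2p = 10^(3 / 2), sigma0_dbv = 10^(1 / 2) / 100,
       plds_s = c(0.9, 1.2, 1.4, 1.8, 2.1), label_duration_s = 2.0,
       t1b_s = 1.65, t1t_s = 1.3, lambda_ml_g = 0.9, alpha = 0.85,
       hbt = 8.441, ya = 0.98)
}

#' Read a configuration file (JSON or flat key=value)
#'
#' JSON files (extension .json) are parsed with jsonlite; anything else is
#' read as flat \code{key = value} lines (comma-separated lists allowed,
#' \code{#} comments stripped). Unknown keys raise an error; missing keys take
#' the \code{\link{default_config}} values.
#'
#' @param path file path.
#' @return named list as in \code{\link{default_config}}.
#' @export
read_config <- function(path) {
  defaults <- default_config()
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
    keys <- trimws(vapply(kv, `[[`, "", 1L))
    vals <- lapply(kv, function(x) {
      as.numeric(trimws(strsplit(x[[2]], ",", fixed = TRUE)[[1]]))
    })
    names(vals) <- keys
  }
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, vals)
}

#' Build protocol objects from a configuration list
#'
#' @param cfg named list as returned by \code{\link{default_config}} or
#'   \code{\link{read_config}}.
#' @return list with components \code{ase}, \code{tissue}, \code{asl},
#'   \code{priors}, \code{metabolic}.
#' @export
config_protocols <- function(cfg = default_config()) {
  list(ase = ase_protocol(te = cfg$te_s, tr = cfg$tr_s, taus = cfg$taus_s,
                          b0 = cfg$b0_T),
       tissue = tissue_constants(gamma = cfg$gamma, dchi0 = cfg$dchi0,
                                 r2t = cfg$r2t_s, hct = cfg$hct),
       asl = asl_protocol(plds = cfg$plds_s,
                          label_duration = cfg$label_duration_s,
                          t1b = cfg$t1b_s, t1t = cfg$t1t_s,
                          lam = cfg$lambda_ml_g, alpha = cfg$alpha),
       priors = prior_spec(mu0_r2p = cfg$mu0_r2p, mu0_dbv = cfg$mu0_dbv,
                           sigma0_r2p = cfg$sigma0_r2p,
                           sigma0_dbv = cfg$sigma0_dbv),
       metabolic = metabolic_constants(hbt = cfg$hbt, ya = cfg$ya))
}
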