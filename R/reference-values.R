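# Published group-level ROI reference values for eight healthy adults
# scanned before (pre) and after (post) acetazolamide vasodilation: mean and
# between-subject SD of CBF (mL/100 g/min), OEF (%), R2' (s^-1), DBV (%) and
# CMRO2 (umol/100 g/min) in nine cortical regions (six default-mode-network
# regions and three non-DMN reference regions). These printed values are an
# input to the package: they parameterize the digital phantom and feed the
# derived summary statistics.

#' Published per-ROI hemodynamic reference table
#'
#' Group mean and between-subject SD per ROI and condition for CBF, OEF,
#' R2', DBV and CMRO2 in nine cortical regions: angular gyrus (AG), medial
#' frontal gyrus (MFG), anterior cingulate gyrus (aCG), posterior cingulate
#' gyrus (pCG), precuneus (PCun), supramarginal gyrus (SG), occipital pole
#' (OP), middle temporal gyrus (MTG), inferior temporal gyrus (ITG).
#' OEF and DBV are in percent, CBF in mL/100 g/min, R2' in s^-1, CMRO2 in
#' umol/100 g/min.
#'
#' @return data.frame with one row per (roi, condition), condition in
#'   \code{c("pre", "post")}, and columns \code{<param>_mean},
#'   \code{<param>_sd}.
#' @export
reference_roi_table <- function() {
  roi <- c("AG", "MFG", "aCG", "pCG", "PCun", "SG", "OP", "MTG", "ITG")
  pre <- data.frame(
    roi = roi, condition = "pre",
    cbf_mean = c(60.7, 43.2, 68.6, 76.3, 61.6, 54.9, 40.0, 54.5, 40.2),
    cbf_sd   = c(15.6, 10.6, 14.5, 14.8, 11.1, 14.1,  9.7, 13.7, 10.7),
    oef_mean = c(44.4, 32.4, 35.9, 34.5, 39.6, 43.2, 30.7, 25.9, 29.3),
    oef_sd   = c( 4.1, 10.9,  4.7,  4.8,  4.2,  5.2,  8.3,  3.0,  3.1),
    r2p_mean = c( 4.8,  9.1,  3.8,  3.7,  4.0,  5.1,  7.1,  7.8, 11.1),
    r2p_sd   = c( 1.0,  2.6,  0.4,  0.3,  0.7,  0.5,  1.6,  1.0,  1.2),
    dbv_mean = c( 3.1, 11.0,  3.2,  3.4,  3.2,  3.1,  7.8, 11.5, 17.6),
    dbv_sd   = c( 0.7,  6.1,  0.4,  0.8,  0.7,  0.9,  2.2,  2.8,  3.1),
    cmro2_mean = c(223.0, 117.1, 206.3, 216.9, 201.7, 194.9, 103.2, 115.6,
                   100.3),
    cmro2_sd   = c(58.2, 47.7, 57.1, 51.8, 43.8, 51.3, 38.9, 28.8, 28.1))
  post <- data.frame(
    roi = roi, condition = "post",
    cbf_mean = c(81.8, 74.8, 93.3, 104.4, 87.6, 76.4, 58.4, 76.1, 57.6),
    cbf_sd   = c(22.4, 23.2, 21.3, 17.8, 18.1, 22.2,  8.8, 20.7, 13.5),
    oef_mean = c(38.2, 30.3, 30.7, 25.7, 30.9, 39.1, 27.2, 25.1, 27.1),
    oef_sd   = c( 3.8, 11.6,  6.5,  4.7,  4.1,  2.5,  7.2,  3.0,  2.3),
    r2p_mean = c( 4.3,  9.0,  3.9,  3.7,  3.6,  4.7,  6.5,  7.1, 10.4),
    r2p_sd   = c( 0.8,  2.1,  0.7,  0.5,  0.7,  0.6,  0.7,  0.8,  1.9),
    dbv_mean = c( 3.5, 12.2,  4.3,  4.5,  3.7,  3.4,  8.2, 10.7, 16.1),
    dbv_sd   = c( 0.7,  6.0,  1.4,  1.3,  0.7,  0.9,  2.1,  2.5,  3.6),
    cmro2_mean = c(260.8, 173.5, 238.4, 221.5, 223.1, 246.7, 130.4, 154.9,
                   130.3),
    cmro2_sd   = c(80.1, 40.6, 82.3, 51.1, 54.0, 70.6, 35.8, 33.5, 35.8))
  rbind(pre, post)
}

#' Canonical ROI names
#'
#' The nine cortical ROI labels used throughout the package, in table order.
#' @return character vector of length 9.
#' @export
canonical_rois <- function() {
  c("AG", "MFG", "aCG", "pCG", "PCun", "SG", "OP", "MTG", "ITG")
}
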