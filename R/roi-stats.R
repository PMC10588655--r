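# ROI aggregation, oxygen metabolism, paired hypothesis testing with
# Bonferroni correction, mixed-effects association between oxygenation and
# perfusion, and the derived group summary statistics.

#' Per-ROI mean, SD and voxel count of a parameter map
#'
#' Averages valid voxels of \code{map} within each positive atlas label.
#' Labels present in \code{labels} but empty (no valid voxel) are returned
#' with NA mean and flagged missing; atlas labels not in \code{labels} are
#' ignored with a warning.
#'
#' @param map 3-D numeric array.
#' @param atlas 3-D integer array of ROI labels (0 = background).
#' @param valid_mask optional 3-D logical array; NA map voxels are always
#'   treated as invalid.
#' @param labels integer labels to report (default: all positive labels in
#'   the atlas).
#' @return data.frame with columns \code{label}, \code{mean}, \code{sd},
#'   \code{n_valid}, \code{missing}.
#' @export
roi_means <- function(map, atlas, valid_mask = NULL, labels = NULL) {
  stopifnot(identical(dim(map), dim(atlas)))
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(map))
  stopifnot(identical(dim(valid_mask), dim(map)))
  present <- sort(unique(as.integer(atlas[atlas > 0])))
  if (is.null(labels)) {
    labels <- present
  } else if (length(setdiff(present, labels))) {
    warning("atlas contains unknown label(s): ",
            paste(setdiff(present, labels), collapse = ", "), " -- ignored")
  }
  ok <- valid_mask & !is.na(map)
  out <- lapply(labels, function(l) {
    v <- map[atlas == l & ok]
    data.frame(label = l, mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_valid = length(v), missing = length(v) == 0)
  })
  do.call(rbind, out)
}

#' Cerebral metabolic rate of oxygen
#'
#' \code{CMRO2 = CBF * OEF * Hba} in umol/100 g/min, with CBF in
#' mL/100 g/min, OEF a fraction, and \code{Hba} the arteriolar oxygenated
#' hemoglobin concentration in umol/mL. Bilinear in CBF and OEF.
#'
#' @param cbf perfusion, mL/100 g/min (>= 0); vectorized.
#' @param oef oxygen extraction fraction as a fraction (>= 0); vectorized.
#' @param const \code{\link{metabolic_constants}}.
#' @return CMRO2 in umol/100 g/min.
#' @export
#' @examples
#' cmro2(76.3, 0.345)  # ~ 217.7
cmro2 <- function(cbf, oef, const = metabolic_constants()) {
  if (any(cbf < 0, na.rm = TRUE) || any(oef < 0, na.rm = TRUE)) {
    stop("cbf and oef must be non-negative")
  }
  cbf * oef * const$hba
}

#' Paired two-sided t-tests with Bonferroni correction
#'
#' One paired t-test per column (ROI) of the subject-by-ROI matrices
#' \code{pre} and \code{post}; two-sided p-values; a result is flagged
#' Bonferroni-significant when \code{p < alpha / n_comparisons}. If all
#' paired differences in a column are zero the test is reported as t = 0,
#' p = 1; zero-variance differences with a non-zero mean give an undefined
#' (NA) p flagged via \code{degenerate}.
#'
#' @param pre,post numeric matrices (subjects x ROIs) or data.frames with
#'   matching dimensions; >= 2 rows.
#' @param n_comparisons Bonferroni family size (default: number of columns).
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with per-ROI \code{mean_diff} (post - pre), \code{t},
#'   \code{df}, \code{p}, \code{significant}, \code{degenerate}.
#' @export
paired_tests <- function(pre, post, n_comparisons = NULL, alpha = 0.05) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post))) stop("pre/post dimensions differ")
  n <- nrow(pre)
  if (n < 2) stop("need at least 2 paired observations")
  m <- ncol(pre)
  if (is.null(n_comparisons)) n_comparisons <- m
  thr <- alpha / n_comparisons
  res <- lapply(seq_len(m), function(j) {
    d <- post[, j] - pre[, j]
    md <- mean(d); sdd <- stats::sd(d)
    if (sdd == 0) {
      if (md == 0) {
        data.frame(t = 0, df = n - 1, p = 1, degenerate = FALSE)
      } else {
        data.frame(t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE)
      }
    } else {
      tt <- md / (sdd / sqrt(n))
      data.frame(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
                 degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  data.frame(roi = colnames(pre) %||% paste0("roi", seq_len(m)),
             mean_diff = colMeans(post) - colMeans(pre),
             t = res$t, df = res$df, p = res$p,
             significant = !is.na(res$p) & res$p < thr,
             degenerate = res$degenerate,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mixed-effects association between a parameter and CBF
#'
#' Random-intercepts linear mixed model
#' \code{dependent ~ cbf + (1 | subject) + (1 | region)} fitted with
#' \code{lme4::lmer} (REML by default), pooling both physiological
#' conditions. The p-value uses a t reference distribution with
#' \code{n - 2} residual degrees of freedom (no small-sample correction).
#'
#' @param dependent numeric response (e.g. OEF in percent, or R2').
#' @param cbf matched CBF values, mL/100 g/min.
#' @param subject,region grouping factors (coerced).
#' @param reml logical; REML (default) or ML.
#' @return object of class \code{lmm_result}: list with \code{beta},
#'   \code{se}, \code{tstat}, \code{pvalue}, \code{varcomp} (subject,
#'   region, residual SDs), \code{singular}, \code{n}.
#' @export
lmm_association <- function(dependent, cbf, subject, region, reml = TRUE) {
  df <- data.frame(y = dependent, cbf = cbf,
                   subject = factor(subject), region = factor(region))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$subject)) < 2 ||
      nlevels(droplevels(df$region)) < 2) {
    stop("need at least 2 subjects and 2 regions")
  }
  fit <- lme4::lmer(y ~ cbf + (1 | subject) + (1 | region), data = df,
                    REML = reml,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  beta <- unname(lme4::fixef(fit)["cbf"])
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["cbf"]]
  tt <- beta / se
  n <- nrow(df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(g) {
    i <- vc$grp == g & is.na(vc$var2)
    if (any(i)) vc$sdcor[i][1] else NA_real_
  }
  structure(list(beta = beta, se = se, tstat = tt,
                 pvalue = 2 * stats::pt(-abs(tt), df = n - 2),
                 varcomp = c(subject = sd_of("subject"),
                             region = sd_of("region"),
                             residual = sd_of("Residual")),
                 singular = lme4::isSingular(fit), n = n),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("beta = %.4f +/- %.4f  (t = %.3f, p = %.4g, n = %d%s)\n",
              x$beta, x$se, x$tstat, x$pvalue, x$n,
              if (x$singular) ", singular fit" else ""))
  invisible(x)
}

#' Assemble a per-ROI, per-condition statistics table
#'
#' From per-subject ROI values (one row per subject x condition x ROI),
#' computes per-(ROI, condition) means and SDs for each parameter, paired
#' pre/post tests with Bonferroni correction, and the subject-level CMRO2
#' (per-subject CBF x OEF x Hba, then averaged -- the product of the
#' condition means is reported separately as \code{cmro2_of_means}).
#'
#' @param per_subject data.frame with columns \code{subject},
#'   \code{condition} ("pre"/"post"), \code{roi}, and parameter columns
#'   \code{cbf} (mL/100 g/min), \code{oef} (percent), optionally \code{r2p}
#'   (s^-1) and \code{dbv} (percent).
#' @param const \code{\link{metabolic_constants}}.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return object of class \code{roi_stats_table}: list with \code{summary}
#'   (data.frame roi x condition x parameter mean/sd), \code{tests}
#'   (data.frame per roi x parameter), \code{n_subjects},
#'   \code{n_comparisons}.
#' @export
roi_stats_table <- function(per_subject, const = metabolic_constants(),
                            alpha = 0.05) {
  need <- c("subject", "condition", "roi", "cbf", "oef")
  if (!all(need %in% names(per_subject))) {
    stop("per_subject must have columns: ", paste(need, collapse = ", "))
  }
  per_subject$cmro2 <- cmro2(per_subject$cbf, per_subject$oef / 100, const)
  params <- intersect(c("cbf", "oef", "r2p", "dbv", "cmro2"),
                      names(per_subject))
  rois <- unique(per_subject$roi)
  n_comp <- length(rois)
  summary <- do.call(rbind, lapply(rois, function(r) {
    do.call(rbind, lapply(c("pre", "post"), function(cond) {
      sel <- per_subject$roi == r & per_subject$condition == cond
      row <- data.frame(roi = r, condition = cond)
      for (p in params) {
        row[[paste0(p, "_mean")]] <- mean(per_subject[[p]][sel])
        row[[paste0(p, "_sd")]] <- stats::sd(per_subject[[p]][sel])
      }
      row
    }))
  }))
  # product-of-means CMRO2 variant for the report
  summary$cmro2_of_means <- cmro2(summary$cbf_mean, summary$oef_mean / 100,
                                  const)
  tests <- do.call(rbind, lapply(params, function(p) {
    wide <- function(cond) {
      sub <- per_subject[per_subject$condition == cond, ]
      tapply(sub[[p]], list(factor(sub$subject),
                            factor(sub$roi, levels = rois)), mean)
    }
    tt <- paired_tests(wide("pre"), wide("post"), n_comparisons = n_comp,
                       alpha = alpha)
    tt$parameter <- p
    tt
  }))
  structure(list(summary = summary, tests = tests,
                 n_subjects = length(unique(per_subject$subject)),
                 n_comparisons = n_comp),
            class = "roi_stats_table")
}

#' Derived group summary statistics
#'
#' From per-ROI group means in both conditions computes: (a) the mean
#' baseline (pre) OEF across ROIs, percent; (b) the mean over ROIs of the
#' per-ROI relative CBF change, \code{(post - pre)/pre * 100}; (c) the mean
#' over ROIs of the per-ROI relative OEF decrease,
#' \code{(pre - post)/pre * 100}; (d) the per-ROI absolute OEF change
#' \code{pre - post} in percentage points.
#'
#' @param table data.frame with columns \code{roi}, \code{condition}
#'   ("pre"/"post"), \code{oef_mean} (percent) and \code{cbf_mean}
#'   (mL/100 g/min) -- e.g. \code{\link{reference_roi_table}} or the
#'   \code{summary} of a \code{\link{roi_stats_table}}.
#' @param required_rois ROIs that must be present (default the canonical
#'   nine); a missing one raises an error naming it.
#' @return list with \code{mean_baseline_oef},
#'   \code{mean_cbf_increase_pct}, \code{mean_oef_decrease_pct}, and
#'   \code{abs_oef_change} (named vector, percentage points).
#' @export
#' @examples
#' s <- summary_changes(reference_roi_table())
#' round(s$mean_baseline_oef, 1)  # 35.1
summary_changes <- function(table, required_rois = canonical_rois()) {
  need <- c("roi", "condition", "oef_mean", "cbf_mean")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  missing_roi <- setdiff(required_rois,
                         intersect(table$roi[table$condition == "pre"],
                                   table$roi[table$condition == "post"]))
  if (length(missing_roi)) {
    stop("missing ROI(s): ", paste(missing_roi, collapse = ", "))
  }
  table <- table[table$roi %in% required_rois, ]
  pre <- table[table$condition == "pre", ]
  post <- table[table$condition == "post", ]
  post <- post[match(pre$roi, post$roi), ]
  list(mean_baseline_oef = mean(pre$oef_mean),
       mean_cbf_increase_pct =
         mean((post$cbf_mean - pre$cbf_mean) / pre$cbf_mean * 100),
       mean_oef_decrease_pct =
         mean((pre$oef_mean - post$oef_mean) / pre$oef_mean * 100),
       abs_oef_change = stats::setNames(pre$oef_mean - post$oef_mean,
                                        pre$roi))
}
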