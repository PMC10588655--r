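test_that("noise-free fit recovers the generating parameters", {
  # at the prior means
  oef0 <- oef_from_r2p_dbv(2.6, 0.036, default_tc, 3)
  y <- make_ase_signal(oef0, 0.036)
  f <- fit_voxel(y, default_ase, default_tc, default_priors)
  expect_true(f$valid)
  expect_equal(unname(f$mean["r2p"]), 2.6, tolerance = 1e-6)
  expect_equal(unname(f$mean["dbv"]), 0.036, tolerance = 1e-6)
  expect_equal(unname(f$mean["s0"]), 1, tolerance = 1e-6)
  # away from the prior means, including a high-DBV truth
  for (tv in list(c(0.45, 0.05), c(0.29, 0.18))) {
    y <- make_ase_signal(tv[1], tv[2])
    f <- fit_voxel(y, default_ase, default_tc, default_priors)
    expect_equal(unname(f$mean["dbv"]), tv[2], tolerance = 1e-4)
    expect_equal(unname(f$mean["r2p"]), truth_r2p(tv[1], tv[2]),
                 tolerance = 1e-4)
  }
})

test_that("degenerate and invalid inputs are handled per contract", {
  # constant signal (no reversible decay): R2' -> 0+, DBV near the prior
  y <- rep(exp(-11.5 * 0.056), length(default_ase$taus))
  f <- fit_voxel(y, default_ase, default_tc, default_priors)
  expect_true(f$valid)
  expect_lt(unname(f$mean["r2p"]), 0.05)
  expect_lt(abs(unname(f$mean["dbv"]) - 0.036), 10^(1 / 2) / 100)
  # all-zero and non-finite signals flag the voxel, no exception
  f0 <- fit_voxel(rep(0, 8), default_ase, default_tc, default_priors)
  expect_false(f0$valid)
  expect_true(all(is.na(f0$mean)))
  fn <- fit_voxel(c(NA, rep(0.5, 7)), default_ase, default_tc,
                  default_priors)
  expect_false(fn$valid)
  # protocol contract
  expect_error(fit_voxel(rep(0.5, 7), ase_protocol(taus = seq(0.016, 0.040,
                                                              0.004))),
               "tau = 0")
  expect_error(fit_voxel(rep(0.5, 3), default_ase), "length")
})

test_that("estimates shrink to the prior means as the assumed noise SD
           grows on a fixed dataset", {
  set.seed(21)
  y <- make_ase_signal(0.5, 0.06) + rnorm(8, 0, 0.002)
  dist <- vapply(c(0.002, 0.02, 0.2, 2, 20), function(s) {
    f <- fit_voxel(y, default_ase, default_tc, default_priors, sigma = s)
    abs(unname(f$mean["dbv"]) - 0.036) / 0.036 +
      abs(unname(f$mean["r2p"]) - 2.6) / 2.6
  }, numeric(1))
  expect_lt(dist[5], 0.05 * dist[1])  # sigma -> Inf: prior means
  expect_true(all(diff(dist) < 1e-9 + 0.02 * dist[1]))  # monotone descent
})

test_that("fit_volume bookkeeping, determinism and tau-count guard", {
  g <- c(4, 4, 3)
  mask <- array(FALSE, g); mask[c(2, 10, 30)] <- TRUE
  taus <- default_ase$taus
  arr <- array(0, c(g, length(taus)))
  y <- make_ase_signal(0.35, 0.04)
  for (k in seq_along(taus)) {
    sl <- array(0, g); sl[mask] <- y[k]; arr[, , , k] <- sl
  }
  m1 <- fit_volume(arr, mask, smooth_sigma_mm = 0)
  expect_identical(sum(m1$valid), 3L)
  expect_true(all(is.na(m1$r2p[!mask])))
  m2 <- fit_volume(arr, mask, smooth_sigma_mm = 0)
  expect_identical(m1$r2p, m2$r2p)      # bit-identical rerun
  m3 <- fit_volume(arr, mask, smooth_sigma_mm = 0, dedupe = FALSE)
  expect_equal(m1$r2p, m3$r2p, tolerance = 1e-15)
  expect_error(fit_volume(arr[, , , 1:5], mask, smooth_sigma_mm = 0),
               "mismatch")
})

test_that("oef_map applies the closed-form relation and flags dbv = 0", {
  maps <- structure(
    list(r2p = array(c(2.6, 0, 5.2, 3), c(2, 2, 1)),
         dbv = array(c(0.036, 0.05, 0.036, 0), c(2, 2, 1)),
         s0 = array(1, c(2, 2, 1)), oef = NULL,
         valid = array(TRUE, c(2, 2, 1)),
         meta = list(shape = c(2, 2, 1), voxel_size_mm = c(1, 1, 1))),
    class = "parameter_maps")
  out <- oef_map(maps, default_tc, 3)
  expect_equal(out$oef[1, 1, 1], 0.2035, tolerance = 1e-3)
  expect_equal(out$oef[2, 1, 1], 0)                      # r2p = 0
  expect_equal(out$oef[1, 2, 1], 2 * out$oef[1, 1, 1],
               tolerance = 1e-12)                        # linear in r2p
  expect_false(out$valid[2, 2, 1])                       # dbv = 0
  expect_true(is.na(out$oef[2, 2, 1]))
})

test_that("physiological exclusion thresholds: strict inequality, report", {
  maps <- structure(
    list(r2p = array(c(2, 20, 21, 3), c(4, 1, 1)),
         dbv = array(0.04, c(4, 1, 1)), s0 = array(1, c(4, 1, 1)),
         oef = array(c(0.5, 1.0, 0.8, 1.2), c(4, 1, 1)),
         valid = array(TRUE, c(4, 1, 1)),
         meta = list(shape = c(4, 1, 1), voxel_size_mm = c(1, 1, 1))),
    class = "parameter_maps")
  ex <- physiological_exclusion(maps)
  # voxel 2: oef = 1.0 exactly and r2p = 20.0 exactly -> retained
  expect_identical(as.vector(ex$maps$valid), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ex$report$pct_excluded_total, 50)
  expect_equal(ex$report$pct_excluded_oef, 25)
  expect_equal(ex$report$pct_excluded_r2p, 25)
  expect_true(is.na(ex$maps$oef[3, 1, 1]))
})

test_that("group average map honors the half-population support rule", {
  g <- c(2, 2, 1)
  mk <- function(val, valid) {
    structure(list(r2p = array(1, g), dbv = array(0.03, g),
                   s0 = array(1, g), oef = array(val, g),
                   valid = array(valid, g),
                   meta = list(shape = g, voxel_size_mm = c(1, 1, 1))),
              class = "parameter_maps")
  }
  subj <- c(lapply(c(0.2, 0.3, 0.4, 0.5), mk, valid = TRUE),
            lapply(rep(0.9, 4), mk, valid = FALSE))
  res <- group_average_map(subj, "oef")
  expect_equal(res$min_support, 4)
  expect_equal(unique(as.vector(res$support)), 4)
  expect_equal(unique(as.vector(res$mean)), 0.35)  # mean of 0.2..0.5
  # 3 of 8 valid -> excluded
  subj3 <- c(subj[1:3], lapply(rep(0.9, 5), mk, valid = FALSE))
  res3 <- group_average_map(subj3, "oef")
  expect_true(all(is.na(res3$mean)))
  # N = 1: group map equals the single subject
  res1 <- group_average_map(subj[1], "oef")
  expect_equal(unique(as.vector(res1$mean)), 0.2)
  expect_error(group_average_map(list(mk(0.2, TRUE),
                                      structure(list(oef = array(1, c(3, 3, 1)),
                                                     valid = array(TRUE, c(3, 3, 1)),
                                                     meta = list(shape = c(3, 3, 1))),
                                                class = "parameter_maps"))),
               "shared grid")
})
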