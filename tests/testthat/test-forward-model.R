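test_that("delta_omega matches direct arithmetic and handles edge cases", {
  expect_identical(delta_omega(0, default_tc, 3), 0)
  # (4*pi/3) * 2.675e8 * 3 * 0.264e-6 * 0.40 * 0.40
  expect_equal(delta_omega(0.40, default_tc, 3), 141.99, tolerance = 1e-4)
  dw <- delta_omega(0.2035, default_tc, 3)
  expect_equal(dw, 72.24, tolerance = 1e-3)
  expect_equal(0.036 * dw, 2.60, tolerance = 1e-3)
  expect_error(delta_omega(-0.1), "non-negative")
  expect_error(delta_omega(1.2), "<= 1")
})

test_that("R2' = DBV * delta_omega round trip is exact", {
  set.seed(11)
  oef <- runif(50, 0.01, 0.99)
  dbv <- runif(50, 0.001, 0.5)
  d <- dephasing_derived(oef, dbv, default_tc, 3)
  expect_equal(d$r2p, dbv * d$delta_omega, tolerance = 1e-15)
  expect_equal(d$tc_boundary / d$tc_small, rep(1.76, 50), tolerance = 1e-15)
  expect_equal(oef_from_r2p_dbv(d$r2p, dbv, default_tc, 3), oef,
               tolerance = 1e-12)
})

test_that("r2b matches the empirical quadratic and is monotone", {
  expect_equal(r2b(0.40, 0), 11.06, tolerance = 1e-12)
  expect_equal(r2b(0.40, 0.40), 11.06 + 121.78 * 0.16, tolerance = 1e-12)
  expect_equal(r2b(0.40, 1), 132.84, tolerance = 1e-10)
  oefs <- seq(0, 1, 0.05)
  expect_true(all(diff(r2b(0.40, oefs)) > 0))
  hcts <- seq(0.2, 0.6, 0.05)
  expect_true(all(diff(r2b(hcts, 0.4)) > 0))
  expect_error(r2b(0, 0.4), "hct")
  expect_error(r2b(0.4, 1.5), "oef")
})

test_that("tissue signal reproduces both regimes of the static-dephasing
           model", {
  st <- voxel_state(1, 0.2035, 0.036)
  # tau = 0: pure R2t decay at TE
  expect_equal(tissue_signal(st, default_tc, default_ase, 0),
               exp(-11.5 * 0.056), tolerance = 1e-12)
  # short-tau quadratic regime (tau < Tc ~ 24.4 ms)
  expect_equal(tissue_signal(st, default_tc, default_ase, 0.016),
               0.5177, tolerance = 2e-4)
  # long-tau linear regime
  expect_equal(tissue_signal(st, default_tc, default_ase, 0.016),
               exp(-0.644) * exp(-0.3 * 0.036 *
                                   (delta_omega(0.2035, default_tc, 3) *
                                      0.016)^2),
               tolerance = 1e-12)
  expect_equal(tissue_signal(st, default_tc, default_ase, 0.040),
               exp(-0.644) * exp(0.036 - 0.036 *
                                   delta_omega(0.2035, default_tc, 3) *
                                   0.040),
               tolerance = 1e-12)
})

test_that("regime branch is chosen per voxel from each voxel's own
           delta_omega", {
  # two voxels whose Tc straddle tau = 28 ms: high-OEF voxel is long-regime,
  # low-OEF voxel still short-regime at the same tau
  st <- voxel_state(1, c(0.15, 0.60), 0.03)
  dw <- delta_omega(c(0.15, 0.60), default_tc, 3)
  tau <- 0.028
  expect_true(tau * dw[1] < 1.76 && tau * dw[2] > 1.76)
  got <- tissue_signal(st, default_tc, default_ase, tau)
  base <- exp(-11.5 * 0.056)
  expect_equal(got[1], base * exp(-0.3 * 0.03 * (dw[1] * tau)^2),
               tolerance = 1e-12)
  expect_equal(got[2], base * exp(0.03 - 0.03 * dw[2] * tau),
               tolerance = 1e-12)
})

test_that("signal is non-negative, finite and non-increasing in R2t", {
  taus <- default_ase$taus
  r2ts <- c(5, 11.5, 20, 40)
  sigs <- vapply(r2ts, function(r) {
    tc <- tissue_constants(r2t = r)
    total_signal(voxel_state(1, 0.4, 0.05), tc, default_ase, taus)
  }, numeric(length(taus)))
  expect_true(all(is.finite(sigs)) && all(sigs >= 0))
  for (i in seq_along(taus)) expect_true(all(diff(sigs[i, ]) < 0))
})

test_that("blood signal: Fresnel limit at tau = 0 and monotone envelope", {
  st <- voxel_state(1, 0.2035, 0.036)
  sb0 <- Mod(blood_signal(st, default_tc, default_ase, 0))
  expect_equal(sb0, exp(-r2b(0.40, 0.2035) * 0.056), tolerance = 1e-12)
  expect_equal(sb0, 0.4059, tolerance = 2e-4)
  taus <- seq(0.004, 0.06, by = 0.004)
  sbs <- Mod(blood_signal(st, default_tc, default_ase, taus))
  expect_true(all(sbs < sb0))
})

test_that("Fresnel closed form equals the powder-average oracle to 1e-6
           over delta_omega * tau in [0, 10]", {
  us <- c(0, 0.05, 0.3, 1, 2, 2.889, 5, 7.5, 10)  # 2.889 = 72.24 * 0.040
  for (u in us) {
    oracle <- powder_average_oracle(if (u == 0) 0 else u / 0.04, 0.04)
    closed <- fresnel_ratio(u) * exp(1i * u / 2)
    expect_lt(Mod(closed - oracle) / max(Mod(oracle), 1e-12), 1e-6)
    expect_lte(Mod(oracle), 1 + 1e-12)
  }
})

test_that("total signal: compartment limits and composition", {
  taus <- default_ase$taus
  st0 <- voxel_state(1, 0.2035, 0)
  expect_equal(total_signal(st0, default_tc, default_ase, taus),
               tissue_signal(st0, default_tc, default_ase, taus),
               tolerance = 1e-15)
  st1 <- voxel_state(2, 0.2035, 0.999999)
  expect_equal(total_signal(st1, default_tc, default_ase, 0.02),
               2 * Mod(blood_signal(st1, default_tc, default_ase, 0.02)),
               tolerance = 1e-4)
  st <- voxel_state(1, 0.2035, 0.036)
  expect_equal(total_signal(st, default_tc, default_ase, 0.040),
               0.036 * Mod(blood_signal(st, default_tc, default_ase, 0.040)) +
                 0.964 * tissue_signal(st, default_tc, default_ase, 0.040),
               tolerance = 1e-15)
})

test_that("protocol and state constructors enforce invariants", {
  expect_error(ase_protocol(te = 0), "te")
  expect_error(ase_protocol(taus = c(0.02, 0.016)))
  expect_error(voxel_state(1, 1.2, 0.03))
  expect_error(voxel_state(1, 0.3, 1))
  expect_error(tissue_constants(hct = 1.2), "hct")
})
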