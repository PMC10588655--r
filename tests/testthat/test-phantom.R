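test_that("default spec transcribes the published per-ROI values", {
  spec <- default_table_spec(seed = 1)
  tab <- spec$roi_table
  get <- function(r, cond, col) tab[tab$roi == r & tab$condition == cond,
                                    col]
  expect_equal(get("pCG", "pre", "cbf_mean"), 76.3)
  expect_equal(get("pCG", "pre", "cbf_sd"), 14.8)
  expect_equal(get("pCG", "pre", "oef_mean"), 34.5)
  expect_equal(get("PCun", "post", "oef_mean"), 30.9)
  expect_equal(get("MTG", "pre", "oef_mean"), 25.9)
  expect_equal(spec$n_subjects, 8L)
  expect_length(spec$rois, 9)
  expect_error(phantom_spec(), "seed")
})

test_that("phantom truth: determinism, SD = 0 exactness, consistency", {
  spec0 <- default_table_spec(seed = 5, sd_scale = 0)
  t1 <- build_phantom(spec0)
  t2 <- build_phantom(spec0)
  expect_identical(t1$roi_truth, t2$roi_truth)
  # SD = 0: every subject's ROI truth equals the spec mean
  tab <- spec0$roi_table
  rt <- t1$roi_truth
  m <- match(paste(rt$roi, rt$condition), paste(tab$roi, tab$condition))
  expect_equal(rt$oef, tab$oef_mean[m] / 100, tolerance = 1e-12)
  expect_equal(rt$cbf, tab$cbf_mean[m], tolerance = 1e-12)
  # R2' truth is derived from (OEF, DBV) through the dephasing relation
  expect_equal(rt$r2p, rt$dbv * delta_omega(rt$oef, default_tc, 3),
               tolerance = 1e-12)
  # post CBF truth exceeds pre in every ROI (vasodilation ordering)
  w <- reshape(rt[rt$subject == 1, c("roi", "condition", "cbf")],
               idvar = "roi", timevar = "condition", direction = "wide")
  expect_true(all(w$cbf.post > w$cbf.pre))
})

test_that("Gaussian sampling: across-subject mean near the spec mean", {
  spec <- default_table_spec(seed = 7)   # full Table SDs
  tr <- build_phantom(spec)$roi_truth
  sel <- tr$roi == "pCG" & tr$condition == "pre"
  mu <- mean(tr$cbf[sel])
  se <- 14.8 / sqrt(8)
  expect_lt(abs(mu - 76.3), 2 * se)
})

test_that("atlas layout is disjoint, labeled 1..9, background 0", {
  t1 <- build_phantom(default_table_spec(seed = 2, sd_scale = 0))
  expect_setequal(unique(as.vector(t1$atlas)), 0:9)
  counts <- table(t1$atlas[t1$atlas > 0])
  expect_true(all(counts == counts[1]))   # equal-size blocks
})

test_that("ASE simulation: bookkeeping, reproducibility, noise scaling", {
  spec <- default_table_spec(seed = 3, n_subjects = 2,
                             grid_shape = c(12, 12, 12), sd_scale = 0)
  truth <- build_phantom(spec)
  sim <- simulate_ase_study(truth, default_ase, snr = Inf)
  expect_length(sim$data, 2)
  expect_identical(dim(sim$data[[1]]$pre)[4], 8L)
  expect_identical(sim$noise_sd, 0)
  # noise-free signal at an ROI voxel equals the forward model at truth
  vox <- which(truth$atlas == 4)[1]
  rt <- subset(truth$roi_truth, subject == 1 & condition == "pre" &
                 roi == "pCG")
  y <- total_signal(voxel_state(1, rt$oef, rt$dbv), default_tc,
                    default_ase, default_ase$taus)
  got <- vapply(1:8, function(k) sim$data[[1]]$pre[, , , k][vox],
                numeric(1))
  expect_equal(got, y, tolerance = 1e-12)
  # seeded noise: reproducible, and different across subjects
  simn1 <- simulate_ase_study(truth, default_ase, snr = 50, seed = 9L)
  simn2 <- simulate_ase_study(truth, default_ase, snr = 50, seed = 9L)
  expect_identical(simn1$data[[1]]$pre, simn2$data[[1]]$pre)
  expect_false(identical(simn1$data[[1]]$pre, simn1$data[[2]]$pre))
  expect_equal(simn1$noise_sd, mean(simn1$data[[1]]$pre[, , , 1][truth$atlas > 0]) / 50,
               tolerance = 0.1)
})

test_that("ASL simulation: 5 PLD volumes, kinetic-model voxels, M0", {
  spec <- default_table_spec(seed = 3, n_subjects = 1,
                             grid_shape = c(12, 12, 12), sd_scale = 0)
  truth <- build_phantom(spec)
  sim <- simulate_asl_study(truth, default_asl, snr = Inf)
  expect_identical(dim(sim$data[[1]]$pre$dm)[4], 5L)
  vox <- which(truth$atlas == 1)[1]
  rt <- subset(truth$roi_truth, subject == 1 & condition == "pre" &
                 roi == "AG")
  y <- asl_signal(perfusion_state(rt$cbf, rt$att, 1), default_asl,
                  default_asl$plds)
  got <- vapply(1:5, function(k) sim$data[[1]]$pre$dm[, , , k][vox],
                numeric(1))
  expect_equal(got, y, tolerance = 1e-12)
  expect_equal(sim$data[[1]]$pre$m0[vox], 1)
})

test_that("ROI statistics are invariant to phantom layout geometry", {
  # same truth values painted on different grids -> identical ROI means
  res <- lapply(c(16, 20), function(n) {
    spec <- default_table_spec(seed = 4, n_subjects = 1,
                               grid_shape = c(n, n, n), sd_scale = 0)
    truth <- build_phantom(spec)
    sim <- simulate_ase_study(truth, default_ase, snr = Inf)
    maps <- fit_volume(sim$data[[1]]$pre, truth$atlas > 0,
                       smooth_sigma_mm = 0)
    maps <- oef_map(maps)
    roi_means(maps$oef, truth$atlas, maps$valid)$mean
  })
  expect_equal(res[[1]], res[[2]], tolerance = 1e-9)
})
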