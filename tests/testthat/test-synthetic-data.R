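test_that("planted kernels act as declared linear systems", {
  # identity kernel: target reproduces source exactly
  co <- tiny_kernel_cohort(h = 1, noise_sd = 0)
  v <- co$subjects[[1]]$ts$values
  expect_equal(v[2, ], v[1, ], tolerance = 1e-12)

  # pure gain
  co <- tiny_kernel_cohort(h = 0.5, noise_sd = 0)
  v <- co$subjects[[1]]$ts$values
  expect_equal(v[2, ], 0.5 * v[1, ], tolerance = 1e-12)

  # 3-tap kernel: DFT(target) = DFT(source) * DFT(zero-padded kernel),
  # checked against a direct DFT of all three sequences
  h <- c(0.6, -0.3, 0.2)
  co <- tiny_kernel_cohort(h = h, noise_sd = 0, n_timepoints = 32)
  v <- co$subjects[[1]]$ts$values
  X <- slow_dft(v[1, ])
  Y <- slow_dft(v[2, ])
  H <- slow_dft(c(h, numeric(32 - 3)))
  expect_equal(Y, X * H, tolerance = 1e-8)
})

test_that("cohorts are bit-identical given the same config", {
  cfg <- demo_sim_config(n_per_group = 2, n_rois = 12, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  # and change under a different seed
  c3 <- generate_cohort(demo_sim_config(n_per_group = 2, n_rois = 12, seed = 100))
  expect_false(identical(c1$subjects[[1]]$ts$values, c3$subjects[[1]]$ts$values))
})

test_that("base signals are zero-mean, unit-variance and band-limited", {
  co <- tiny_kernel_cohort(h = 1, n_rois = 6, n_timepoints = 130, seed = 5)
  f <- corrtf:::fft_freqs(130, 3)
  out_band <- !(abs(f) >= 0.01 & abs(f) <= 0.08)
  for (r in 3:6) {  # untouched base ROIs
    x <- co$subjects[[1]]$ts$values[r, ]
    expect_lt(abs(mean(x)), 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-12)
    p <- Mod(fft(x))^2
    expect_lt(sum(p[out_band]) / sum(p), 0.01)
  }
})

test_that("configuration errors are caught", {
  expect_error(kernel_spec(1, 1, 1), "must differ")
  expect_error(kernel_spec(1, 2, numeric(0)), "tap")
  expect_error(
    sim_config(groups = list(NC = list(n = 1, kernels = list(kernel_spec(1, 9, 1)))),
               n_rois = 4),
    "out of range"
  )
  # feedback loop 1 -> 2 -> 1 is rejected
  expect_error(
    sim_config(groups = list(NC = list(n = 1, kernels = list(
      kernel_spec(1, 2, 1), kernel_spec(2, 1, 1)))), n_rois = 4),
    "cycle"
  )
  expect_error(
    sim_config(groups = list(SICK = list(n = 1)), n_rois = 4),
    "unknown group label"
  )
  expect_error(sim_config(groups = list(NC = list(n = 1)), n_timepoints = 8),
               ">= 16")
})

test_that("kernel chains compose in topological order", {
  h1 <- c(0.8, 0.2); h2 <- c(0.5, -0.5)
  cfg <- sim_config(groups = list(NC = list(n = 1, kernels = list(
    kernel_spec(2, 3, h2),   # listed before its upstream edge on purpose
    kernel_spec(1, 2, h1)
  ))), n_rois = 3, n_timepoints = 32, seed = 2)
  v <- generate_cohort(cfg)$subjects[[1]]$ts$values
  H1 <- fft(c(h1, numeric(30))); H2 <- fft(c(h2, numeric(30)))
  expect_equal(fft(v[3, ]), fft(v[1, ]) * H1 * H2, tolerance = 1e-8)
})

test_that("ground-truth edges are the between-group differing kernels", {
  cfg <- demo_sim_config(n_per_group = 1, n_rois = 116)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth_edges
  # three discriminative edges; the two shared edges are excluded
  expect_equal(nrow(gt), 3)
  expect_false(any(gt[, "source"] %in% c(1, 3)))
})

test_that("labeled volumes round-trip through voxel averaging", {
  co <- tiny_kernel_cohort(h = 1, n_rois = 2, n_timepoints = 24)
  ts <- co$subjects[[1]]$ts
  for (vpr in c(1, 8)) {
    lay <- block_layout(2, voxels_per_roi = vpr)
    vol <- generate_labeled_volume(ts, lay)
    rec <- extract_mean_timeseries(vol$bold, vol$labels, discard_initial = 0)
    expect_equal(rec$values, ts$values, tolerance = 1e-12)
    expect_equal(rec$roi_ids, ts$roi_ids)
  }
})

test_that("voxel noise averages down as the standard error of the mean", {
  co <- tiny_kernel_cohort(h = 1, n_rois = 2, n_timepoints = 100, seed = 21)
  ts <- co$subjects[[1]]$ts
  nvox <- 64; noise_sd <- 0.8
  set.seed(31)
  lay <- block_layout(2, voxels_per_roi = nvox)
  vol <- generate_labeled_volume(ts, lay, voxel_noise_sd = noise_sd)
  rec <- extract_mean_timeseries(vol$bold, vol$labels, discard_initial = 0)
  err <- rec$values - ts$values
  sem <- noise_sd / sqrt(nvox)
  # empirical RMS error should sit near the SEM (chi spread over 200 cells)
  expect_lt(sqrt(mean(err^2)), 1.3 * sem)
  expect_gt(sqrt(mean(err^2)), 0.7 * sem)
})

test_that("overlapping voxel blocks are rejected", {
  co <- tiny_kernel_cohort(h = 1, n_rois = 2, n_timepoints = 24)
  lay <- block_layout(2, voxels_per_roi = 2)
  lay$blocks[["2"]] <- c(2L, 3L)  # overlaps block 1
  expect_error(generate_labeled_volume(co$subjects[[1]]$ts, lay), "overlap")
})

test_that("cohort TSV round trip preserves subjects and labels", {
  co <- generate_cohort(demo_sim_config(n_per_group = 2, n_rois = 12, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), length(co$subjects))
  expect_equal(vapply(back$subjects, `[[`, character(1), "label"),
               vapply(co$subjects, `[[`, character(1), "label"))
  expect_equal(back$subjects[[3]]$ts$values, co$subjects[[3]]$ts$values,
               tolerance = 1e-10)
})
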