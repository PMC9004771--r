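test_that("corrtf_pair obeys identity, gain and the DFT shift theorem", {
  set.seed(20)
  x <- rnorm(48)
  r <- corrtf_pair(x, x)
  expect_equal(unname(r[!attr(r, "guarded")]),
               rep(1 + 0i, sum(!attr(r, "guarded"))), tolerance = 1e-10)

  # y = 2x -> ratio 0.5 everywhere unguarded
  r <- corrtf_pair(x, 2 * x)
  expect_equal(unique(round(r[!attr(r, "guarded")], 10)), 0.5 + 0i)

  # circular shift by d: bin k = exp(+2*pi*i*k*d/T) with unit magnitude,
  # cross-checked against the direct DFT of both series
  d <- 5; n <- 48
  y <- x[c((n - d + 1):n, 1:(n - d))]   # x delayed by d samples
  r <- corrtf_pair(y, x)
  k <- 0:(n - 1)
  expected <- exp(-2i * pi * k * d / n)
  direct <- slow_dft(y) / slow_dft(x)
  ok <- !attr(r, "guarded")
  expect_equal(unname(r[ok]), expected[ok], tolerance = 1e-8)
  expect_equal(unname(r[ok]), direct[ok], tolerance = 1e-8)
  expect_equal(Mod(r[ok]), rep(1, sum(ok)), tolerance = 1e-10)
})

test_that("corrtf_pair guards tiny denominators and validates input", {
  expect_error(corrtf_pair(rnorm(10), rnorm(12)), "length mismatch")
  expect_error(corrtf_pair(numeric(10), numeric(10), guard = 0), "all-zero")
  r <- corrtf_pair(rnorm(16), numeric(16))  # guard active: all flagged zero
  expect_true(all(attr(r, "guarded")))
  expect_true(all(r == 0))
})

test_that("corrtf_tensor has full-DFT shape and the algebraic identities", {
  co <- tiny_kernel_cohort(h = c(0.4, 0.1), n_rois = 5, n_timepoints = 40,
                           seed = 22)
  ts <- co$subjects[[1]]$ts
  tn <- corrtf_tensor(ts)
  expect_equal(dim(tn), c(5, 5, 40))
  g <- attr(tn, "denom_guarded")

  # diagonal is exactly 1 at unguarded bins
  for (i in 1:5) {
    expect_equal(unname(tn[i, i, !g[i, ]]),
                 rep(1 + 0i, sum(!g[i, ])), tolerance = 1e-12)
  }
  # reciprocal identity values[i,j,k] * values[j,i,k] = 1 where both
  # denominators are live
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !g[i, ] & !g[j, ]
    expect_equal(unname(tn[i, j, ok] * tn[j, i, ok]),
                 rep(1 + 0i, sum(ok)), tolerance = 1e-8)
  }
  # tensor rows match corrtf_pair
  r <- corrtf_pair(ts$values[3, ], ts$values[2, ])
  expect_equal(unname(tn[3, 2, ]), as.vector(r), tolerance = 1e-10)
})

test_that("scaling one ROI rescales its ratio row and column reciprocally", {
  co <- tiny_kernel_cohort(h = 1, n_rois = 4, n_timepoints = 32, seed = 23)
  ts <- co$subjects[[1]]$ts
  alpha <- 2.5
  ts2 <- ts; ts2$values[3, ] <- alpha * ts2$values[3, ]
  t1 <- corrtf_tensor(ts); t2 <- corrtf_tensor(ts2)
  g <- attr(t1, "denom_guarded")
  for (j in c(1, 2, 4)) {
    ok <- !g[j, ]
    expect_equal(Mod(t2[3, j, ok]), alpha * Mod(t1[3, j, ok]), tolerance = 1e-8)
    ok3 <- !g[3, ]
    expect_equal(Mod(t2[j, 3, ok3]), Mod(t1[j, 3, ok3]) / alpha, tolerance = 1e-8)
  }
})

test_that("noise-free planted kernels are recovered at every bin", {
  h <- c(0.5, 0.2, -0.7)           # zero DC gain: sum(h) = 0
  co <- tiny_kernel_cohort(h = h, noise_sd = 0, n_rois = 6,
                           n_timepoints = 130, seed = 24)
  tn <- corrtf_tensor(co$subjects[[1]]$ts)
  H <- fft(c(h, numeric(130 - length(h))))
  expect_lt(max(abs(Mod(tn[2, 1, ]) - Mod(H))), 1e-6)
})

test_that("kernel recovery error shrinks monotonically with noise", {
  h <- c(0.5, 0.2, -0.7)
  H <- Mod(fft(c(h, numeric(130 - 3))))
  f <- corrtf:::fft_freqs(130, 3)
  inband <- abs(f) >= 0.01 & abs(f) <= 0.08
  mae <- vapply(c(0.5, 0.1, 0.02), function(nsd) {
    co <- tiny_kernel_cohort(h = h, noise_sd = nsd, n_rois = 4,
                             n_timepoints = 130, seed = 25)
    tn <- corrtf_tensor(co$subjects[[1]]$ts)
    mean(abs(Mod(tn[2, 1, inband]) - H[inband]))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("fisher_z matches arctanh with clipping and counts clipped cells", {
  a <- array(complex(modulus = c(0, 0.5, 1, 3), argument = 0), c(1, 2, 2))
  z <- fisher_z(a)
  expect_equal(z[1, 1, 1], 0)
  expect_equal(z[1, 2, 1], 0.5 * log(3), tolerance = 1e-12)  # arctanh(0.5)
  expect_equal(z[1, 1, 2], atanh(1 - 1e-6))
  expect_true(all(is.finite(z)))
  expect_equal(attr(z, "n_clipped"), 2)  # |1| and |3| both clipped

  # real-part variant clips symmetrically
  zr <- fisher_z(array(-2 + 0i, c(1, 1, 1)), transform = "real")
  expect_equal(as.numeric(zr), atanh(-(1 - 1e-6)))
})

test_that("frequency averaging is the arithmetic bin mean with a zeroed diagonal", {
  z <- array(0.3, c(3, 3, 4))
  m <- average_over_freq(z)
  expect_equal(unclass(m)[1, 2], 0.3)
  expect_equal(diag(unclass(m)), rep(0, 3))
  expect_true(attr(m, "diagonal_excluded"))

  z[1, 2, ] <- c(0.2, 0.6, 0.2, 0.6)
  expect_equal(unclass(average_over_freq(z))[1, 2], 0.4)

  # band-limited averaging keeps only in-band bins
  attr(z, "freq_hz") <- c(0, 0.04, 0.12, -0.04)
  z[1, 3, ] <- 1:4
  mb <- average_over_freq(z, band_limited = TRUE)
  expect_equal(unclass(mb)[1, 3], mean(c(2, 4)))
})

test_that("subject_features equals the composed tensor pipeline", {
  co <- tiny_kernel_cohort(h = c(0.4, 0.3), noise_sd = 0.2, n_rois = 6,
                           n_timepoints = 50, seed = 26)
  ts <- co$subjects[[1]]$ts
  v <- subject_features(ts)
  expect_length(v, 6 * 5)
  # independent one-shot oracle: mean_k arctanh(clip(|DFT_i / DFT_j|))
  m <- average_over_freq(fisher_z(corrtf_tensor(ts)))
  expect_equal(as.numeric(v), unclass(m)[attr(v, "edges")], tolerance = 1e-12)
  # determinism
  expect_identical(v, subject_features(ts))
})

test_that("features are equivariant under consistent ROI permutation", {
  co <- tiny_kernel_cohort(h = c(0.7, -0.2), n_rois = 5, n_timepoints = 40,
                           seed = 27)
  ts <- co$subjects[[1]]$ts
  perm <- c(3, 1, 5, 2, 4)
  ts2 <- roi_timeseries(ts$values[perm, ], roi_ids = ts$roi_ids[perm],
                        tr_seconds = ts$tr_seconds)
  m1 <- corrtf:::edges_to_matrix(as.numeric(subject_features(ts)),
                                 corrtf:::edge_index(5), 5)
  m2 <- corrtf:::edges_to_matrix(as.numeric(subject_features(ts2)),
                                 corrtf:::edge_index(5), 5)
  expect_equal(m2, m1[perm, perm], tolerance = 1e-12)
})

test_that("cohort feature tables round-trip through TSV", {
  co <- generate_cohort(demo_sim_config(n_per_group = 2, n_rois = 12, seed = 6))
  fs <- cohort_features(co)
  expect_equal(dim(fs$x), c(8, 12 * 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fs, f)
  back <- read_feature_tsv(f)
  expect_equal(back$x, fs$x, tolerance = 1e-10)
  expect_equal(back$edges, fs$edges)
  expect_equal(back$labels, fs$labels)
})
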