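# Shared fixture builders; everything is generated in code at test time.

# tiny single-group cohort with one planted kernel edge
tiny_kernel_cohort <- function(h, noise_sd = 0, n_rois = 4, n_timepoints = 64,
                               seed = 11, source = 1, target = 2, n = 1) {
  cfg <- sim_config(
    groups = list(NC = list(n = n, kernels = list(
      kernel_spec(source, target, h, noise_sd)
    ))),
    n_rois = n_rois, n_timepoints = n_timepoints, seed = seed
  )
  generate_cohort(cfg)
}

# feature matrices drawn edgewise from N(mu, 1); planted edges get a mean
# shift of `shift` (in pooled-SD units, since SD = 1) in group B
feature_group <- function(n, n_edges, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * n_edges, mean = mu), nrow = n)
}

# a feature_set over R ROIs with planted mean differences per group, built
# directly at the feature level (fast stand-in for the full signal pipeline)
planted_feature_set <- function(n_per_group, n_rois, planted, shift,
                                groups = c("NC", "AD"), seed = 1) {
  set.seed(seed)
  e <- corrtf:::edge_index(n_rois)
  n_edges <- nrow(e)
  x <- NULL
  labels <- character(0)
  for (gi in seq_along(groups)) {
    xg <- matrix(rnorm(n_per_group * n_edges), nrow = n_per_group)
    if (gi > 1) xg[, planted] <- xg[, planted] + shift * (gi - 1)
    x <- rbind(x, xg)
    labels <- c(labels, rep(groups[gi], n_per_group))
  }
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  structure(list(x = x, edges = e, roi_ids = seq_len(n_rois), labels = labels),
            class = "feature_set")
}

# direct (brute-force) DFT, the oracle for everything fft-based
slow_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * k / n))
  }, complex(1))
}
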