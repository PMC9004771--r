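#' Planted transfer-function kernel
#'
#' Declares that one ROI's signal is generated from another's through a
#' finite impulse response (FIR) kernel: the target series is the circular
#' convolution of the source series with `impulse_response`, plus white
#' Gaussian observation noise. In the frequency domain the planted transfer
#' function is the DFT of the zero-padded kernel, which is exactly what the
#' CorrTF ratio recovers in the noise-free case.
#'
#' @param source_roi,target_roi 1-based ROI indices, distinct.
#' @param impulse_response numeric vector of FIR taps, at least one, finite.
#' @param noise_sd standard deviation of additive observation noise on the
#'   target series (signal units; base signals are unit variance).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(source_roi, target_roi, impulse_response, noise_sd = 0) {
  if (length(impulse_response) < 1 || !all(is.finite(impulse_response))) {
    stop("impulse_response needs >= 1 finite tap")
  }
  if (source_roi == target_roi) stop("source_roi and target_roi must differ")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(source_roi = as.integer(source_roi),
                 target_roi = as.integer(target_roi),
                 impulse_response = as.numeric(impulse_response),
                 noise_sd = as.numeric(noise_sd)),
            class = "kernel_spec")
}

#' Simulation configuration for a synthetic rs-fMRI cohort
#'
#' Describes a multi-group cohort of band-limited ROI time series. Defaults
#' mirror the target acquisition: 116 atlas regions, TR = 3 s, 130 retained
#' time points, passband 0.01-0.08 Hz. Group differences are encoded as
#' group-specific kernels on a shared edge set; kernels within a group must
#' form a DAG over ROIs (targets are processed in topological order, so
#' chains are allowed but feedback loops are not).
#'
#' @param groups named list: one entry per diagnostic label (subset of
#'   NC/EMCI/LMCI/AD), each a list with `n` (subject count) and `kernels`
#'   (list of [kernel_spec()], possibly empty).
#' @param n_rois number of ROIs (default 116).
#' @param n_timepoints retained time points (default 130, minimum 16).
#' @param tr_seconds repetition time in seconds (default 3).
#' @param passband two frequencies in Hz, `0 < low < high < Nyquist`.
#' @param seed integer RNG seed; identical configs generate bit-identical
#'   cohorts.
#' @param leakage out-of-band amplitude floor of the base signals, relative
#'   to in-band gain 1. Keeps every non-DC DFT bin observable (so spectral
#'   ratios are defined at all bins) while out-of-band power stays around
#'   `leakage^2` of total, far below the 1% spectral-support bound.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(groups, n_rois = 116, n_timepoints = 130, tr_seconds = 3,
                       passband = c(0.01, 0.08), seed = 1, leakage = 1e-3) {
  if (n_timepoints < 16) stop("n_timepoints must be >= 16")
  nyq <- 1 / (2 * tr_seconds)
  if (!(passband[1] > 0 && passband[1] < passband[2] && passband[2] < nyq)) {
    stop("need 0 < low_hz < high_hz < Nyquist = ", signif(nyq, 4), " Hz")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list of diagnostic labels")
  }
  bad <- setdiff(names(groups), stage_levels)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (is.null(grp$n) || grp$n < 1) stop("group ", g, " needs n >= 1")
    kernels <- grp$kernels %||% list()
    for (ks in kernels) {
      if (!inherits(ks, "kernel_spec")) stop("kernels must be kernel_spec objects")
      if (ks$source_roi < 1 || ks$source_roi > n_rois ||
          ks$target_roi < 1 || ks$target_roi > n_rois) {
        stop("kernel ROI index out of range in group ", g, ": ",
             ks$source_roi, " -> ", ks$target_roi)
      }
    }
    assert_dag(kernels, g)
  }
  structure(list(groups = groups, n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, passband = passband,
                 seed = as.integer(seed), leakage = leakage),
            class = "sim_config")
}

# topological ordering of kernel list; error on cycles or duplicate targets
assert_dag <- function(kernels, group = "") {
  if (length(kernels) == 0) return(integer(0))
  tgt <- vapply(kernels, function(k) k$target_roi, integer(1))
  src <- vapply(kernels, function(k) k$source_roi, integer(1))
  if (anyDuplicated(tgt)) {
    stop("group ", group, ": multiple kernels share a target ROI")
  }
  order <- integer(0)
  remaining <- seq_along(kernels)
  repeat {
    # a kernel is ready when its source is not the target of a remaining kernel
    ready <- remaining[!(src[remaining] %in% tgt[remaining])]
    if (length(ready) == 0) {
      if (length(remaining) == 0) break
      stop("group ", group, ": kernel graph contains a cycle (must be a DAG)")
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
    if (length(remaining) == 0) break
  }
  order
}

# unit-variance, exactly zero-mean base signal, band-limited with a small
# out-of-band leakage floor
base_signal <- function(n, tr, passband, leakage) {
  f <- fft_freqs(n, tr)
  gain <- ifelse(abs(f) >= passband[1] & abs(f) <= passband[2], 1, leakage)
  x <- rnorm(n)
  y <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

circ_convolve <- function(x, h) {
  n <- length(x)
  hp <- c(h, numeric(n - length(h)))
  Re(fft(fft(x) * fft(hp), inverse = TRUE)) / n
}

#' Generate a synthetic cohort with planted transfer functions
#'
#' Base ROI signals are white Gaussian noise band-limited to the passband and
#' z-scored (exactly zero mean, unit variance). For every kernel edge, the
#' target ROI's series is replaced by the circular convolution of its source
#' series with the kernel taps plus Gaussian observation noise, processed in
#' topological order so kernel chains compose. The generator is fully
#' deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: list with `subjects` (each a
#'   list of `subject_id`, `label`, `ts`), `ground_truth_edges` (integer
#'   matrix of directed source -> target pairs whose kernel differs between
#'   at least two groups), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_timepoints
  subjects <- list()
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    kernels <- grp$kernels %||% list()
    topo <- assert_dag(kernels, g)
    for (s in seq_len(grp$n)) {
      vals <- t(vapply(seq_len(config$n_rois), function(i) {
        base_signal(n, config$tr_seconds, config$passband, config$leakage)
      }, numeric(n)))
      for (ki in topo) {
        ks <- kernels[[ki]]
        y <- circ_convolve(vals[ks$source_roi, ], ks$impulse_response)
        if (ks$noise_sd > 0) y <- y + rnorm(n, sd = ks$noise_sd)
        vals[ks$target_roi, ] <- y
      }
      subjects[[length(subjects) + 1L]] <- list(
        subject_id = sprintf("%s_%03d", g, s),
        label = g,
        ts = roi_timeseries(vals, roi_ids = seq_len(config$n_rois),
                            tr_seconds = config$tr_seconds)
      )
    }
  }
  structure(list(subjects = subjects,
                 ground_truth_edges = differing_edges(config$groups),
                 config = config),
            class = "synthetic_cohort")
}

# directed edges whose kernel signature (taps + noise) differs across groups,
# including presence/absence differences
differing_edges <- function(groups) {
  sig <- list()
  edges <- character(0)
  for (g in names(groups)) {
    for (ks in groups[[g]]$kernels %||% list()) {
      key <- paste(ks$source_roi, ks$target_roi, sep = "->")
      edges <- union(edges, key)
      sig[[g]][[key]] <- paste(c(ks$impulse_response, ks$noise_sd), collapse = ",")
    }
  }
  differ <- vapply(edges, function(key) {
    sigs <- vapply(names(groups), function(g) sig[[g]][[key]] %||% "<absent>",
                   character(1))
    length(unique(sigs)) > 1
  }, logical(1))
  keys <- edges[differ]
  if (length(keys) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("source", "target"))))
  }
  parts <- do.call(rbind, strsplit(keys, "->", fixed = TRUE))
  m <- cbind(source = as.integer(parts[, 1]), target = as.integer(parts[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, character(1), "label")
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d ROIs x %d time points\n",
              length(labs), paste(sprintf("%s=%d", names(table(labs)),
                                          table(labs)), collapse = ", "),
              x$config$n_rois, x$config$n_timepoints))
  cat(sprintf("  %d ground-truth differing edge(s)\n", nrow(x$ground_truth_edges)))
  invisible(x)
}

#' Rectangular ROI-to-voxel block layout
#'
#' Assigns each ROI a contiguous run of `voxels_per_roi` voxels along the x
#' axis of a minimal 3D grid. Convenience for building labeled test volumes.
#'
#' @param n_rois number of ROIs.
#' @param voxels_per_roi voxels per ROI block.
#' @return layout list with `dim` and `blocks` (named list of linear voxel
#'   indices keyed by ROI index).
#' @export
block_layout <- function(n_rois, voxels_per_roi = 1) {
  nx <- n_rois * voxels_per_roi
  blocks <- lapply(seq_len(n_rois), function(i) {
    ((i - 1L) * voxels_per_roi + 1L):(i * voxels_per_roi)
  })
  names(blocks) <- as.character(seq_len(n_rois))
  list(dim = c(nx, 1L, 1L), blocks = blocks)
}

#' Build a labeled 4D volume from an ROI time series
#'
#' Fills each ROI's voxel block with that ROI's signal value at each time
#' point (constant fill, so the voxel mean reproduces the series exactly),
#' optionally adding independent per-voxel Gaussian noise. Intended as a
#' fixture generator for [extract_mean_timeseries()] round trips.
#'
#' @param ts [roi_timeseries()].
#' @param layout list with `dim` (3D grid size) and `blocks` (named list, ROI
#'   index -> linear voxel indices). Blocks must not overlap and every ROI in
#'   `ts` needs at least one voxel.
#' @param voxel_noise_sd per-voxel noise SD added on top of the fill.
#' @return list with `bold` (4D array) and `labels` (3D integer array; 0 =
#'   background).
#' @export
generate_labeled_volume <- function(ts, layout, voxel_noise_sd = 0) {
  stopifnot(inherits(ts, "roi_timeseries"))
  vdim <- as.integer(layout$dim)
  nvox <- prod(vdim)
  all_idx <- unlist(layout$blocks, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("overlapping voxel blocks in layout")
  if (any(all_idx < 1 | all_idx > nvox)) stop("voxel index outside grid")
  n_t <- ncol(ts$values)
  labels <- integer(nvox)
  bold <- matrix(0, nrow = nvox, ncol = n_t)
  for (r in seq_along(ts$roi_ids)) {
    idx <- layout$blocks[[as.character(r)]]
    if (is.null(idx) || length(idx) == 0) {
      stop("layout has no voxels for ROI ", r)
    }
    labels[idx] <- ts$roi_ids[r]
    fill <- matrix(ts$values[r, ], nrow = length(idx), ncol = n_t, byrow = TRUE)
    if (voxel_noise_sd > 0) {
      fill <- fill + matrix(rnorm(length(idx) * n_t, sd = voxel_noise_sd),
                            nrow = length(idx))
    }
    bold[idx, ] <- fill
  }
  list(bold = array(bold, c(vdim, n_t)), labels = array(labels, vdim))
}

#' Write a cohort to disk as plain-text TSVs
#'
#' One ROI x time TSV per subject plus a `labels.tsv` (subject_id, label).
#'
#' @param cohort a `synthetic_cohort` (or any list of subjects in the same
#'   shape).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    label = vapply(cohort$subjects, `[[`, character(1), "label")
  )
  for (s in cohort$subjects) {
    write_roi_tsv(s$ts, file.path(dir, paste0(s$subject_id, ".tsv")))
  }
  write.table(labs, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param tr_seconds sampling interval for the loaded series.
#' @export
read_cohort <- function(dir, tr_seconds = 3) {
  labs <- read.delim(file.path(dir, "labels.tsv"))
  subjects <- lapply(seq_len(nrow(labs)), function(i) {
    list(subject_id = labs$subject_id[i], label = labs$label[i],
         ts = read_roi_tsv(file.path(dir, paste0(labs$subject_id[i], ".tsv")),
                           tr_seconds = tr_seconds))
  })
  structure(list(subjects = subjects,
                 ground_truth_edges = matrix(integer(0), ncol = 2),
                 config = NULL),
            class = "synthetic_cohort")
}

#' Four-group demonstration cohort configuration
#'
#' A stated-world default exercising the full staging pipeline: four groups
#' (NC, EMCI, LMCI, AD) share three planted edges whose kernel gains differ
#' between groups in a hierarchy-aligned way -- one edge separates AD from
#' the rest, one separates NC from the MCI stages, one separates EMCI from
#' LMCI -- plus two edges identical across groups (non-discriminative
#' "anatomy"). Kernel taps are `gain * c(0.7, 0.2, 0.1)`; observation noise
#' SD is 0.5 against unit-variance signals, a deliberately noisy but
#' realistic ROI-level SNR for band-passed BOLD data.
#'
#' @param n_per_group subjects per group (default 40).
#' @param n_rois number of ROIs (default 116).
#' @param seed RNG seed.
#' @param noise_sd observation noise SD on planted targets (default 0.5).
#' @return a [sim_config()].
#' @export
demo_sim_config <- function(n_per_group = 40, n_rois = 116, seed = 1,
                            noise_sd = 0.5) {
  if (n_rois < 12) stop("demo config needs at least 12 ROIs")
  taps <- function(g) g * c(0.7, 0.2, 0.1)
  # edge roles (1-based ROI indices, chosen among AAL-order limbic/DMN-ish
  # regions when n_rois = 116, but any index set works)
  eA <- c(min(37, n_rois - 5), min(67, n_rois - 4))  # AD-separating
  eB <- c(min(35, n_rois - 3), min(25, n_rois - 2))  # NC-separating
  eC <- c(min(41, n_rois - 1), min(85, n_rois))      # EMCI/LMCI-separating
  eD <- c(1, 2)                                      # shared, identical
  eE <- c(3, 4)
  mk <- function(gA, gB, gC) list(
    kernel_spec(eA[1], eA[2], taps(gA), noise_sd),
    kernel_spec(eB[1], eB[2], taps(gB), noise_sd),
    kernel_spec(eC[1], eC[2], taps(gC), noise_sd),
    kernel_spec(eD[1], eD[2], taps(0.5), noise_sd),
    kernel_spec(eE[1], eE[2], taps(0.5), noise_sd)
  )
  sim_config(
    groups = list(
      NC   = list(n = n_per_group, kernels = mk(0.3, 0.9, 0.6)),
      EMCI = list(n = n_per_group, kernels = mk(0.3, 0.3, 0.9)),
      LMCI = list(n = n_per_group, kernels = mk(0.3, 0.3, 0.3)),
      AD   = list(n = n_per_group, kernels = mk(0.9, 0.3, 0.6))
    ),
    n_rois = n_rois, seed = seed
  )
}
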