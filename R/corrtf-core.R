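#' Spectral ratio between two time series
#'
#' The correlation transfer function of a pair of signals: bin `k` of the
#' result is `DFT(x)[k] / DFT(y)[k]`. When `y` drives `x` through a linear
#' time-invariant path, the ratio is the path's transfer function `H(f)`
#' evaluated at the DFT bins. Bins where the denominator magnitude falls
#' below `guard` times its maximum are set to `0 + 0i` and flagged rather
#' than divided: after band-pass filtering, out-of-band denominator bins are
#' numerically negligible and unguarded division would produce huge,
#' meaningless ratios.
#'
#' @param x,y numeric vectors of common length `T >= 2`.
#' @param guard relative denominator threshold (default `1e-8`); set to 0 to
#'   disable, in which case an all-zero `y` is an error.
#' @return complex vector of length `T`, with a logical attribute `guarded`
#'   marking suppressed bins.
#' @export
corrtf_pair <- function(x, y, guard = 1e-8) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 2) stop("need at least 2 time points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  X <- fft(x)
  Y <- fft(y)
  my <- Mod(Y)
  top <- max(my)
  if (top == 0 && guard <= 0) stop("all-zero denominator series with guard disabled")
  guarded <- if (guard > 0) my <= guard * top else rep(FALSE, length(y))
  r <- complex(length.out = length(x))
  r[!guarded] <- X[!guarded] / Y[!guarded]
  attr(r, "guarded") <- guarded
  r
}

#' CorrTF tensor of an ROI time series
#'
#' Computes the full R x R x T complex array of pairwise spectral ratios:
#' `values[i, j, k] = DFT(row i)[k] / DFT(row j)[k]`, with the denominator
#' guard of [corrtf_pair()] applied per denominator ROI. The third dimension
#' is the full DFT length, so a 116-ROI, 130-time-point subject yields a
#' 116 x 116 x 130 tensor. At unguarded bins the tensor satisfies the
#' reciprocal identity `values[i,j,k] * values[j,i,k] = 1` and the diagonal
#' is exactly `1 + 0i`.
#'
#' @param ts [roi_timeseries()].
#' @param guard relative denominator threshold, as in [corrtf_pair()].
#' @return object of class `corrtf_tensor`: complex array with attributes
#'   `freq_hz` (bin frequencies, fft order), `roi_ids`, and `denom_guarded`
#'   (R x T logical; row j marks bins guarded whenever ROI j is the
#'   denominator).
#' @export
corrtf_tensor <- function(ts, guard = 1e-8) {
  stopifnot(inherits(ts, "roi_timeseries"))
  R <- nrow(ts$values)
  n <- ncol(ts$values)
  X <- t(mvfft(t(ts$values)))           # R x T complex
  m <- Mod(X)
  top <- apply(m, 1, max)
  if (any(top == 0) && guard <= 0) {
    stop("ROI ", which(top == 0)[1], " has an all-zero series with guard disabled")
  }
  denom_guarded <- if (guard > 0) m <= guard * top else
    matrix(FALSE, R, n)
  vals <- array(complex(1), dim = c(R, R, n))
  for (k in seq_len(n)) {
    inv <- complex(length.out = R)
    ok <- !denom_guarded[, k]
    inv[ok] <- 1 / X[ok, k]
    vals[, , k] <- outer(X[, k], inv)   # guarded denominators give 0 columns
  }
  structure(vals,
            freq_hz = fft_freqs(n, ts$tr_seconds),
            roi_ids = ts$roi_ids,
            denom_guarded = denom_guarded,
            class = "corrtf_tensor")
}

#' @export
print.corrtf_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<corrtf_tensor> %d x %d ROIs x %d frequency bins (%d guarded denominator bins)\n",
              d[1], d[2], d[3], sum(attr(x, "denom_guarded"))))
  invisible(x)
}

#' Fisher r-to-z transform of a CorrTF tensor
#'
#' Converts the complex ratios to real values via `arctanh`. The complex to
#' real reduction takes the ratio magnitude by default -- the gain of the
#' transfer path, the quantity interpreted as connection strength -- with the
#' real part available as an alternative. Magnitudes can exceed 1, where
#' `arctanh` is undefined, so values are clipped to `1 - eps_clip` (in
#' absolute value) before transforming; the number of clipped entries is
#' recorded in the `n_clipped` attribute.
#'
#' @param tensor a [corrtf_tensor()] (or bare complex/numeric array).
#' @param eps_clip clip margin below 1 (default `1e-6`).
#' @param transform `"magnitude"` (default) or `"real"`.
#' @return real array of the same shape with attributes `n_clipped`,
#'   `freq_hz` and `roi_ids` carried over.
#' @export
fisher_z <- function(tensor, eps_clip = 1e-6, transform = c("magnitude", "real")) {
  transform <- match.arg(transform)
  v <- if (transform == "magnitude") Mod(tensor) else Re(tensor)
  lim <- 1 - eps_clip
  clipped <- abs(v) > lim
  v[clipped] <- sign(v[clipped]) * lim
  z <- atanh(v)
  attr(z, "n_clipped") <- sum(clipped)
  attr(z, "freq_hz") <- attr(tensor, "freq_hz")
  attr(z, "roi_ids") <- attr(tensor, "roi_ids")
  z
}

#' Average a z-transformed tensor over frequency
#'
#' Collapses the frequency dimension by the arithmetic mean -- over all bins
#' by default, or only over bins inside a passband -- yielding the final
#' R x R connectivity feature matrix. The diagonal is zeroed and flagged as
#' excluded.
#'
#' @param z_tensor real R x R x F array from [fisher_z()].
#' @param band_limited if `TRUE`, average only bins whose `|freq|` lies in
#'   `band` (requires the `freq_hz` attribute).
#' @param band passband in Hz used when `band_limited = TRUE`.
#' @return matrix of class `conn_matrix` with attributes `roi_ids` and
#'   `diagonal_excluded = TRUE`.
#' @export
average_over_freq <- function(z_tensor, band_limited = FALSE,
                              band = c(0.01, 0.08)) {
  d <- dim(z_tensor)
  if (length(d) != 3) stop("expected an R x R x F array")
  bins <- seq_len(d[3])
  if (band_limited) {
    f <- attr(z_tensor, "freq_hz")
    if (is.null(f)) stop("band_limited averaging needs the freq_hz attribute")
    bins <- which(abs(f) >= band[1] & abs(f) <= band[2])
    if (length(bins) == 0) stop("no frequency bins inside the band")
  }
  m <- apply(z_tensor[, , bins, drop = FALSE], c(1, 2), mean)
  diag(m) <- 0
  structure(m, roi_ids = attr(z_tensor, "roi_ids"), diagonal_excluded = TRUE,
            class = c("conn_matrix", "matrix"))
}

#' Per-subject CorrTF feature vector
#'
#' Composes [corrtf_tensor()], [fisher_z()] and [average_over_freq()] without
#' materializing the full tensor, then flattens the off-diagonal cells of the
#' R x R feature matrix in row-major order -- an ordering shared by every
#' subject, so vectors are directly comparable across a cohort. For R = 116
#' the vector has length 116 * 115 = 13340.
#'
#' @inheritParams corrtf_tensor
#' @inheritParams fisher_z
#' @inheritParams average_over_freq
#' @return numeric vector with attributes `edges` (E x 2 integer matrix of
#'   (i, j) cell indices) and `roi_ids`.
#' @export
subject_features <- function(ts, guard = 1e-8, eps_clip = 1e-6,
                             transform = c("magnitude", "real"),
                             band_limited = FALSE, band = c(0.01, 0.08)) {
  transform <- match.arg(transform)
  stopifnot(inherits(ts, "roi_timeseries"))
  R <- nrow(ts$values)
  n <- ncol(ts$values)
  X <- t(mvfft(t(ts$values)))
  m <- Mod(X)
  top <- apply(m, 1, max)
  denom_guarded <- m <= guard * top
  bins <- seq_len(n)
  if (band_limited) {
    f <- fft_freqs(n, ts$tr_seconds)
    bins <- which(abs(f) >= band[1] & abs(f) <= band[2])
  }
  lim <- 1 - eps_clip
  acc <- matrix(0, R, R)
  for (k in bins) {
    inv <- complex(length.out = R)
    ok <- !denom_guarded[, k]
    inv[ok] <- 1 / X[ok, k]
    ratio <- outer(X[, k], inv)
    v <- if (transform == "magnitude") Mod(ratio) else Re(ratio)
    v[abs(v) > lim] <- sign(v[abs(v) > lim]) * lim
    acc <- acc + atanh(v)
  }
  mat <- acc / length(bins)
  diag(mat) <- 0
  e <- edge_index(R)
  structure(mat[e], edges = e, roi_ids = ts$roi_ids)
}

#' Cohort-level feature set
#'
#' Applies [subject_features()] to every subject of a cohort and stacks the
#' vectors into a subjects x edges matrix -- the input to feature selection
#' and classification.
#'
#' @param cohort a `synthetic_cohort` (or list with a `subjects` element of
#'   `(subject_id, label, ts)` entries).
#' @param ... passed to [subject_features()].
#' @return object of class `feature_set`: list with `x` (n x E matrix, rows
#'   named by subject), `edges`, `roi_ids`, `labels` (character vector).
#' @export
cohort_features <- function(cohort, ...) {
  subj <- cohort$subjects
  stopifnot(length(subj) > 0)
  vecs <- lapply(subj, function(s) subject_features(s$ts, ...))
  e <- attr(vecs[[1]], "edges")
  x <- do.call(rbind, lapply(vecs, as.numeric))
  rownames(x) <- vapply(subj, `[[`, character(1), "subject_id")
  structure(list(x = x, edges = e, roi_ids = attr(vecs[[1]], "roi_ids"),
                 labels = vapply(subj, `[[`, character(1), "label")),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d subjects x %d edges (%d ROIs)\n",
              nrow(x$x), ncol(x$x), length(x$roi_ids)))
  invisible(x)
}

#' Write / read a cohort feature table
#'
#' Subjects x edges TSV with a `subject_id` and `label` column followed by
#' one column per directed edge, named `e<i>_<j>`.
#'
#' @param fs a `feature_set`.
#' @param path output path.
#' @export
write_feature_tsv <- function(fs, path) {
  df <- data.frame(subject_id = rownames(fs$x), label = fs$labels, fs$x,
                   check.names = FALSE)
  colnames(df) <- c("subject_id", "label",
                    paste0("e", fs$edges[, 1], "_", fs$edges[, 2]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  en <- colnames(df)[-(1:2)]
  parts <- do.call(rbind, strsplit(sub("^e", "", en), "_"))
  e <- cbind(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]))
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject_id
  colnames(x) <- NULL
  structure(list(x = x, edges = e, roi_ids = seq_len(max(e)),
                 labels = df$label),
            class = "feature_set")
}

# rebuild an R x R matrix from an edge-ordered vector (diag = diag_value)
edges_to_matrix <- function(values, edges, n_rois, diag_value = 0) {
  m <- matrix(diag_value, n_rois, n_rois)
  m[edges] <- values
  m
}
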