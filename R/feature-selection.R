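#' Edge-wise two-sample t-test between two groups
#'
#' Welch's two-sided two-sample t-test applied independently to every
#' directed edge of the CorrTF feature matrices of two groups. Directed
#' edges (i, j) and (j, i) are tested separately (the spectral-ratio tensor
#' is asymmetric). Edges with zero variance in both groups are degenerate:
#' their p-value is set to 1 and they are flagged. No multiple-testing
#' correction is applied by default, matching the plain p < 0.05 selection
#' convention for this feature family; see [select_features()] for an
#' optional FDR adjustment.
#'
#' @param features_a,features_b numeric n x E matrices (rows = subjects,
#'   columns = edges in the shared row-major edge order), or `feature_set`
#'   objects restricted beforehand. Both need >= 2 rows and equal E.
#' @param edges E x 2 integer matrix of edge indices; taken from the
#'   `feature_set` or the `edges` attribute when omitted.
#' @param group_a,group_b optional labels recorded in the result.
#' @return object of class `pvalue_matrix`: an R x R numeric matrix with the
#'   diagonal `NA`, plus attributes `degenerate` (logical R x R),
#'   `group_a`, `group_b`, `n_a`, `n_b`, `edges`.
#' @export
ttest_connections <- function(features_a, features_b, edges = NULL,
                              group_a = "A", group_b = "B") {
  a <- if (inherits(features_a, "feature_set")) features_a$x else features_a
  b <- if (inherits(features_b, "feature_set")) features_b$x else features_b
  if (is.null(edges)) {
    edges <- if (inherits(features_a, "feature_set")) features_a$edges else
      attr(features_a, "edges")
  }
  if (is.null(edges)) stop("edge index required (edges argument or attribute)")
  if (ncol(a) != ncol(b)) stop("edge count mismatch between groups")
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 subjects per group")
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - matrix(ma, na, length(ma), byrow = TRUE))^2) / (na - 1)
  vb <- colSums((b - matrix(mb, nb, length(mb), byrow = TRUE))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degen <- se2 == 0
  p <- rep(1, length(ma))
  if (any(!degen)) {
    tt <- (ma[!degen] - mb[!degen]) / sqrt(se2[!degen])
    df <- se2[!degen]^2 /
      ((va[!degen] / na)^2 / (na - 1) + (vb[!degen] / nb)^2 / (nb - 1))
    p[!degen] <- 2 * pt(-abs(tt), df)
  }
  R <- max(edges)
  pm <- edges_to_matrix(p, edges, R, diag_value = NA_real_)
  dg <- edges_to_matrix(degen, edges, R, diag_value = NA) > 0
  structure(pm, degenerate = dg, group_a = group_a, group_b = group_b,
            n_a = na, n_b = nb, edges = edges,
            class = c("pvalue_matrix", "matrix"))
}

#' Select significant connections
#'
#' Thresholds a p-value matrix at `alpha` with strict inequality
#' (`p < alpha`). Selection is monotone in `alpha`.
#'
#' @param pvals a `pvalue_matrix` from [ttest_connections()].
#' @param alpha significance threshold (default 0.05).
#' @param fdr if `TRUE`, apply a Benjamini-Hochberg adjustment to the
#'   off-diagonal p-values before thresholding (off by default: the
#'   selection convention for this feature family is the raw p < 0.05).
#' @return logical R x R mask of class `connection_mask` (diagonal `FALSE`)
#'   with attributes `alpha` and `n_selected`. An empty selection triggers a
#'   warning; downstream classifiers fall back to all edges.
#' @export
select_features <- function(pvals, alpha = 0.05, fdr = FALSE) {
  p <- unclass(pvals)
  if (fdr) {
    off <- !is.na(p)
    p[off] <- stats::p.adjust(p[off], method = "BH")
  }
  mask <- !is.na(p) & p < alpha
  if (sum(mask) == 0) {
    warning("no edge passed alpha = ", alpha,
            "; classifiers will fall back to all edges")
  }
  structure(mask, alpha = alpha, n_selected = sum(mask),
            class = c("connection_mask", "matrix"))
}

#' Rank the most discriminative connections
#'
#' Orders off-diagonal edges by ascending p-value, breaking ties by
#' row-major edge index, and returns the top `k` with their ROI labels --
#' the format of a "most discriminative connections" table.
#'
#' @param pvals a `pvalue_matrix`.
#' @param k number of edges to return (default 20). If `k` exceeds the
#'   number of available edges, all are returned with a warning.
#' @param roi_names optional character labels (e.g. AAL region names) used
#'   for the `roi_a` / `roi_b` columns; defaults to the ROI indices.
#' @return data.frame with columns `rank`, `roi_a`, `roi_b`, `p_value`.
#' @export
rank_discriminative <- function(pvals, k = 20, roi_names = NULL) {
  edges <- attr(pvals, "edges")
  p <- unclass(pvals)[edges]
  if (k > length(p)) {
    warning("k = ", k, " exceeds the ", length(p), " available edges")
    k <- length(p)
  }
  ord <- order(p, seq_along(p))[seq_len(k)]
  nm <- function(idx) if (is.null(roi_names)) idx else roi_names[idx]
  data.frame(rank = seq_len(k),
             roi_a = nm(edges[ord, 1]),
             roi_b = nm(edges[ord, 2]),
             p_value = p[ord])
}

# group-vs-group convenience on a feature_set
group_ttest <- function(fs, group_a, group_b) {
  ia <- fs$labels == group_a
  ib <- fs$labels == group_b
  ttest_connections(fs$x[ia, , drop = FALSE], fs$x[ib, , drop = FALSE],
                    edges = fs$edges, group_a = group_a, group_b = group_b)
}
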