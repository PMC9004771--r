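#' Group-mean connectivity matrix
#'
#' Elementwise mean of the per-subject R x R feature matrices of one
#' diagnostic group -- the group-level summary thresholded by
#' [threshold_edges()].
#'
#' @param matrices list of R x R matrices with identical ROI ordering, or a
#'   `feature_set` plus `group` to average that group's subjects.
#' @param group diagnostic label, when a `feature_set` is given.
#' @return `conn_matrix` with the common `roi_ids`.
#' @export
group_mean_matrix <- function(matrices, group = NULL) {
  if (inherits(matrices, "feature_set")) {
    fs <- matrices
    if (is.null(group)) stop("group label required with a feature_set")
    sel <- fs$labels == group
    if (!any(sel)) stop("no subjects with label ", group)
    vals <- colMeans(fs$x[sel, , drop = FALSE])
    m <- edges_to_matrix(vals, fs$edges, length(fs$roi_ids))
    return(structure(m, roi_ids = fs$roi_ids, diagonal_excluded = TRUE,
                     class = c("conn_matrix", "matrix")))
  }
  stopifnot(length(matrices) >= 1)
  ids <- attr(matrices[[1]], "roi_ids")
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(matrices[[1]])) ||
        !identical(attr(m, "roi_ids"), ids)) {
      stop("mixed ROI orderings across subject matrices")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(avg, roi_ids = ids %||% seq_len(nrow(avg)),
            diagonal_excluded = TRUE, class = c("conn_matrix", "matrix"))
}

#' Threshold a connectivity matrix into an undirected edge set
#'
#' Keeps the undirected pair (i, j), i < j, whenever either direction
#' reaches the strength threshold, with the larger of the two directed
#' values as the edge strength (directionality ignored; the boundary is
#' inclusive, `>= threshold`). Connection strength here is the group-mean
#' Fisher-z CorrTF value.
#'
#' @param matrix R x R numeric matrix.
#' @param threshold minimum retained strength (default 0.1).
#' @return data.frame of class `edge_set` with columns `roi_a`, `roi_b`
#'   (1-based indices, `roi_a < roi_b`) and `strength`, plus attributes
#'   `roi_ids` and `threshold`.
#' @export
threshold_edges <- function(matrix, threshold = 0.1) {
  m <- unclass(matrix)
  if (!all(is.finite(m))) stop("non-finite entries in connectivity matrix")
  und <- pmax(m, t(m))
  keep <- which(upper.tri(und) & und >= threshold, arr.ind = TRUE)
  out <- data.frame(roi_a = keep[, 1], roi_b = keep[, 2],
                    strength = und[keep])
  out <- out[order(out$roi_a, out$roi_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, roi_ids = attr(matrix, "roi_ids") %||% seq_len(nrow(m)),
            threshold = threshold, class = c("edge_set", "data.frame"))
}

#' Bundled AAL-116 to brain-network mapping
#'
#' A reconstruction assigning each of the 116 AAL atlas regions to one of
#' six networks: sensorimotor cortex (SMC), visual cortex (VC), executive
#' attention network (EAN), default-mode network (DMN), subcortical nuclei
#' (SN) and cerebellum (Cereb). The assignment follows common usage and the
#' region lists named for each network in the staging literature; it is a
#' documented reconstruction, editable as a TSV, not ground truth.
#'
#' @param path optional path to an alternative mapping TSV with columns
#'   `roi_id`, `roi_label`, `network`.
#' @return data.frame with columns `roi_id`, `roi_label`, `network`.
#' @export
aal116_networks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal116_networks.tsv", package = "corrtf",
                        mustWork = TRUE)
  }
  map <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "roi_label", "network")
  if (!all(need %in% colnames(map))) {
    stop("mapping TSV needs columns: ", paste(need, collapse = ", "))
  }
  map
}

#' Count supra-threshold connections per network pair
#'
#' Tallies the edges of an [threshold_edges()] set by the network membership
#' of their endpoints: cell (P, Q) counts edges with one endpoint in network
#' P and the other in Q. Within-network edges are counted once, on the
#' diagonal, so the upper triangle (diagonal included) sums to the total
#' number of edges. The matrix is symmetric.
#'
#' @param edges an `edge_set`.
#' @param mapping data.frame from [aal116_networks()] (or same columns);
#'   every ROI index appearing in `edges` must be mapped exactly once.
#' @return symmetric integer matrix, networks x networks.
#' @export
count_network_pairs <- function(edges, mapping = aal116_networks()) {
  nets <- sort(unique(mapping$network))
  roi_net <- setNames(mapping$network, mapping$roi_id)
  counts <- matrix(0L, length(nets), length(nets),
                   dimnames = list(nets, nets))
  for (r in seq_len(nrow(edges))) {
    ids <- attr(edges, "roi_ids")
    a <- as.character(ids[edges$roi_a[r]])
    b <- as.character(ids[edges$roi_b[r]])
    if (is.na(roi_net[a])) stop("ROI ", a, " is not in the network mapping")
    if (is.na(roi_net[b])) stop("ROI ", b, " is not in the network mapping")
    p <- roi_net[[a]]; q <- roi_net[[b]]
    counts[p, q] <- counts[p, q] + 1L
    if (p != q) counts[q, p] <- counts[q, p] + 1L
  }
  counts
}

#' Export an edge set as viewer-ready node and edge files
#'
#' Writes a plain-text node table (`roi_id`, `label`, `network`, optional
#' `x`, `y`, `z` coordinates) and a weighted adjacency matrix over the
#' mapped ROIs -- the layout common connectome viewers ingest. The pair of
#' files round-trips through [read_edge_list()].
#'
#' @param edges an `edge_set`.
#' @param node_file,edge_file output paths.
#' @param mapping network mapping as in [count_network_pairs()].
#' @param coordinates optional data.frame with `roi_id`, `x`, `y`, `z`; an
#'   edge-set ROI missing from it is an error.
#' @return invisibly, the two paths.
#' @export
export_edge_list <- function(edges, node_file, edge_file,
                             mapping = aal116_networks(), coordinates = NULL) {
  ids <- attr(edges, "roi_ids")
  nodes <- mapping[match(ids, mapping$roi_id), , drop = FALSE]
  if (any(is.na(nodes$roi_id))) {
    stop("ROI ", ids[which(is.na(nodes$roi_id))[1]], " missing from mapping")
  }
  if (!is.null(coordinates)) {
    idx <- match(ids, coordinates$roi_id)
    if (any(is.na(idx))) {
      stop("coordinate table missing ROI ", ids[which(is.na(idx))[1]])
    }
    nodes <- cbind(nodes, coordinates[idx, c("x", "y", "z"), drop = FALSE])
  }
  write.table(nodes, node_file, sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(edges) > 0) {
    adj[cbind(edges$roi_a, edges$roi_b)] <- edges$strength
    adj[cbind(edges$roi_b, edges$roi_a)] <- edges$strength
  }
  write.table(adj, edge_file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(node_file, edge_file))
}

#' @rdname export_edge_list
#' @param threshold strength threshold recorded on the reloaded edge set.
#' @export
read_edge_list <- function(node_file, edge_file, threshold = 0.1) {
  nodes <- read.delim(node_file)
  adj <- as.matrix(read.delim(edge_file, header = FALSE))
  dimnames(adj) <- NULL
  structure(threshold_edges(structure(adj, roi_ids = nodes$roi_id),
                            threshold = threshold),
            roi_ids = nodes$roi_id, threshold = threshold,
            class = c("edge_set", "data.frame"))
}
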