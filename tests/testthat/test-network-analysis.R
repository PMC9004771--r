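make_conn <- function(m, ids = seq_len(nrow(m))) {
  structure(m, roi_ids = ids, diagonal_excluded = TRUE,
            class = c("conn_matrix", "matrix"))
}

test_that("group means average subject matrices elementwise", {
  a <- make_conn(matrix(0.2, 3, 3)); b <- make_conn(matrix(0.4, 3, 3))
  gm <- group_mean_matrix(list(a, b))
  expect_equal(unclass(gm)[1, 2], 0.3)
  expect_equal(unclass(group_mean_matrix(list(a, a))), unclass(a))
  # brute-force oracle over a stack of random matrices
  set.seed(70)
  ms <- lapply(1:5, function(i) make_conn(matrix(rnorm(16), 4)))
  gm <- group_mean_matrix(ms)
  stack <- simplify2array(lapply(ms, unclass))
  expect_equal(unclass(gm), apply(stack, c(1, 2), mean), tolerance = 1e-12,
               ignore_attr = TRUE)
  # mixed ROI orderings are rejected
  c2 <- make_conn(matrix(0.1, 3, 3), ids = c(2, 1, 3))
  expect_error(group_mean_matrix(list(a, c2)), "orderings")
  # feature_set route equals matrix route
  fs <- planted_feature_set(3, 4, planted = integer(0), shift = 0, seed = 71)
  gm2 <- group_mean_matrix(fs, group = "NC")
  direct <- corrtf:::edges_to_matrix(colMeans(fs$x[fs$labels == "NC", ]),
                                     fs$edges, 4)
  expect_equal(unclass(gm2), direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("thresholding keeps undirected pairs by the max-direction rule", {
  m <- matrix(0, 4, 4)
  expect_equal(nrow(threshold_edges(m)), 0)

  m[2, 3] <- 0.05; m[3, 2] <- 0.15       # one direction above threshold
  m[1, 4] <- 0.1                          # boundary: inclusive
  m[1, 2] <- 0.09; m[2, 1] <- 0.09        # both below
  ed <- threshold_edges(m, threshold = 0.1)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$strength[ed$roi_a == 2 & ed$roi_b == 3], 0.15)
  expect_true(any(ed$roi_a == 1 & ed$roi_b == 4))

  # brute-force pair scan oracle on a random matrix
  set.seed(72)
  r <- matrix(runif(36, -0.2, 0.3), 6)
  ed <- threshold_edges(r, threshold = 0.1)
  brute <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    s <- max(r[i, j], r[j, i])
    if (s >= 0.1) brute[[length(brute) + 1]] <- c(i, j, s)
  }
  brute <- do.call(rbind, brute)
  expect_equal(as.matrix(ed[, c("roi_a", "roi_b", "strength")]),
               brute, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("edge counts are non-increasing in the threshold", {
  set.seed(73)
  r <- matrix(runif(100, -0.1, 0.4), 10)
  counts <- vapply(c(0, 0.1, 0.2, 0.3, 0.5),
                   function(th) nrow(threshold_edges(r, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("network-pair counting tallies endpoints and totals correctly", {
  mapping <- data.frame(roi_id = 1:6,
                        roi_label = paste0("R", 1:6),
                        network = c("SMC", "SMC", "VC", "SN", "SN", "SN"))
  m <- matrix(0, 6, 6)
  m[1, 3] <- 0.2                 # SMC-VC
  m[4, 5] <- 0.3; m[5, 6] <- 0.4 # two within SN
  ed <- threshold_edges(m)
  ct <- count_network_pairs(ed, mapping)
  expect_equal(ct["SMC", "VC"], 1L)
  expect_equal(ct["VC", "SMC"], 1L)
  expect_equal(ct["SN", "SN"], 2L)
  expect_equal(ct, t(ct))
  # grand total (upper triangle incl. diagonal) equals the edge count
  expect_equal(sum(ct[upper.tri(ct, diag = TRUE)]), nrow(ed))
  # unmapped ROI is named in the error
  expect_error(count_network_pairs(ed, mapping[-3, ]), "3")

  # random edge set against a per-edge tally oracle
  set.seed(74)
  r <- matrix(runif(36, 0, 0.3), 6)
  ed <- threshold_edges(r)
  ct <- count_network_pairs(ed, mapping)
  expect_equal(sum(ct[upper.tri(ct, diag = TRUE)]), nrow(ed))
  for (p in c("SMC", "VC", "SN")) for (q in c("SMC", "VC", "SN")) {
    nets <- setNames(mapping$network, mapping$roi_id)
    tal <- sum((nets[as.character(ed$roi_a)] == p &
                nets[as.character(ed$roi_b)] == q) |
               (nets[as.character(ed$roi_a)] == q &
                nets[as.character(ed$roi_b)] == p))
    if (p == q) {
      expect_equal(ct[p, q], sum(nets[as.character(ed$roi_a)] == p &
                                 nets[as.character(ed$roi_b)] == p))
    } else {
      expect_equal(ct[p, q], tal)
    }
  }
})

test_that("the bundled AAL mapping covers 116 ROIs across six networks", {
  map <- aal116_networks()
  expect_equal(nrow(map), 116)
  expect_equal(map$roi_id, 1:116)
  expect_setequal(unique(map$network),
                  c("SMC", "VC", "EAN", "DMN", "SN", "Cereb"))
  expect_false(anyDuplicated(map$roi_label) > 0)
})

test_that("edge lists export and re-import losslessly", {
  mapping <- data.frame(roi_id = 1:4, roi_label = paste0("R", 1:4),
                        network = c("VC", "VC", "SN", "SN"))
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.5; m[3, 4] <- 0.12; m[1, 3] <- 0.3
  ed <- threshold_edges(m)
  nf <- withr::local_tempfile(fileext = ".tsv")
  ef <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(ed, nf, ef, mapping = mapping)
  back <- read_edge_list(nf, ef)
  expect_equal(as.data.frame(back), as.data.frame(ed), tolerance = 1e-12)

  # empty set produces a header-only node file and an all-zero adjacency
  ed0 <- threshold_edges(matrix(0, 4, 4))
  export_edge_list(ed0, nf, ef, mapping = mapping)
  expect_equal(nrow(read_edge_list(nf, ef)), 0)

  # coordinates must cover every ROI
  coords <- data.frame(roi_id = 1:3, x = 1:3, y = 1:3, z = 1:3)
  expect_error(export_edge_list(ed, nf, ef, mapping = mapping,
                                coordinates = coords), "4")
})
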