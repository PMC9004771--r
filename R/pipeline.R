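#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Every default matches the
#' convention of the target protocol where one exists: 10 discarded volumes,
#' 0.01-0.08 Hz passband, edge selection at p < 0.05, connection-strength
#' threshold 0.1, 10 cross-validation folds.
#'
#' @param config named list or path to a JSON file. Recognized fields:
#'   `cohort_dir` (directory of ROI TSVs + labels.tsv) *or* `simulate`
#'   (list passed to [demo_sim_config()]: `n_per_group`, `n_rois`, `seed`,
#'   `noise_sd`); `out_dir`; `passband`; `discard_initial`; `alpha`;
#'   `threshold`; `folds`; `seed`; `scheme` ("hierarchical", "flat" or
#'   "both"); `svm_cost`; `band_limited`; `paper_mode`; `contrast`
#'   (two labels for the ranked-edge report, default NC vs AD).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(
    cohort_dir = NULL,
    simulate = list(n_per_group = 40, n_rois = 116, seed = 1, noise_sd = 0.5),
    out_dir = "corrtf_out",
    passband = c(0.01, 0.08),
    tr_seconds = 3,
    discard_initial = 10,
    alpha = 0.05,
    threshold = 0.1,
    folds = 10,
    seed = 42,
    scheme = "both",
    svm_cost = 1,
    band_limited = FALSE,
    paper_mode = FALSE,
    contrast = c("NC", "AD"),
    top_k = 20
  )
  cfg <- utils::modifyList(defaults, config)
  nyq <- 1 / (2 * cfg$tr_seconds)
  if (!(cfg$passband[1] > 0 && cfg$passband[1] < cfg$passband[2] &&
        cfg$passband[2] < nyq)) {
    stop("invalid passband: need 0 < low < high < Nyquist = ", signif(nyq, 4),
         " Hz")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$folds < 2) stop("folds must be >= 2")
  if (!cfg$scheme %in% c("hierarchical", "flat", "both")) {
    stop("scheme must be hierarchical, flat or both")
  }
  if (cfg$discard_initial < 0) stop("discard_initial must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the staging pipeline end to end
#'
#' Executes the stages in order -- cohort input (loaded or simulated),
#' CorrTF feature extraction, t-test edge selection and ranking,
#' cross-validated classification, network-level edge analysis -- and writes
#' a report bundle to `out_dir`: `metrics.json`, one pooled confusion TSV
#' per scheme, `ranked_edges.tsv` for the configured contrast,
#' `network_counts_<group>.tsv` per group, and a `manifest.json` carrying
#' the package version and a hash of the configuration for provenance.
#'
#' @param config a [pipeline_config()] (or the list/path accepted by it).
#' @return invisibly, a list with the feature set, CV results, ranked edges
#'   and network counts.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[corrtf] %-14s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("input", {
    if (!is.null(cfg$cohort_dir)) {
      read_cohort(cfg$cohort_dir, tr_seconds = cfg$tr_seconds)
    } else {
      generate_cohort(do.call(demo_sim_config, cfg$simulate))
    }
  })
  fs <- stage("features", {
    cohort_features(cohort, band_limited = cfg$band_limited,
                    band = cfg$passband)
  })
  ranked <- stage("selection", {
    pv <- group_ttest(fs, cfg$contrast[1], cfg$contrast[2])
    n_rois <- length(fs$roi_ids)
    roi_names <- if (n_rois == 116) aal116_networks()$roi_label else NULL
    rk <- rank_discriminative(pv, k = min(cfg$top_k, sum(!is.na(pv))),
                              roi_names = roi_names)
    write.table(rk, file.path(cfg$out_dir, "ranked_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rk
  })
  schemes <- if (cfg$scheme == "both") c("hierarchical", "flat") else cfg$scheme
  cvs <- stage("classification", {
    res <- lapply(schemes, function(sc) {
      cv <- crossvalidate(fs, scheme = sc, k = cfg$folds, seed = cfg$seed,
                          alpha = cfg$alpha, C = cfg$svm_cost,
                          paper_mode = cfg$paper_mode)
      write.table(cv$confusion,
                  file.path(cfg$out_dir, paste0("confusion_", sc, ".tsv")),
                  sep = "\t", quote = FALSE)
      cv
    })
    names(res) <- schemes
    res
  })
  counts <- stage("network", {
    groups <- unique(fs$labels)
    mapping <- if (length(fs$roi_ids) == 116) aal116_networks() else
      data.frame(roi_id = fs$roi_ids,
                 roi_label = paste0("ROI_", fs$roi_ids),
                 network = "ALL")
    res <- lapply(groups, function(g) {
      gm <- group_mean_matrix(fs, group = g)
      ed <- threshold_edges(gm, threshold = cfg$threshold)
      ct <- count_network_pairs(ed, mapping)
      write.table(ct, file.path(cfg$out_dir,
                                paste0("network_counts_", g, ".tsv")),
                  sep = "\t", quote = FALSE)
      export_edge_list(ed,
                       file.path(cfg$out_dir, paste0("nodes_", g, ".tsv")),
                       file.path(cfg$out_dir, paste0("edges_", g, ".tsv")),
                       mapping = mapping)
      ct
    })
    names(res) <- groups
    res
  })

  metrics <- lapply(cvs, function(cv) list(
    scheme = cv$scheme,
    pooled_accuracy = cv$pooled$accuracy,
    per_fold = cv$metrics$per_fold,
    mean = as.list(cv$metrics$mean),
    sd = as.list(cv$metrics$sd),
    confusion = unclass(cv$confusion)
  ))
  report <- list(version = as.character(packageVersion("corrtf")),
                 config_hash = config_hash(cfg),
                 metrics = metrics)
  jsonlite::write_json(report, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(version = report$version,
                            config_hash = report$config_hash,
                            config = unclass(cfg)),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = fs, cv = cvs, ranked_edges = ranked,
                 network_counts = counts, config = cfg))
}

# md5 of the canonical JSON serialization of the config; output location is
# excluded so reruns into different directories hash identically
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
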