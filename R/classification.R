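#' Hierarchical classification scheme
#'
#' Ordered binary splits routing a subject to exactly one of the four
#' diagnostic stages. The default tree classifies the most separable
#' contrasts first: AD against everything else, then NC against the pooled
#' MCI stages, then EMCI against LMCI. Each layer is a
#' `(positive_class_set, negative_class_set, name)` triple; the sets within
#' a layer are disjoint and the union along any decision path is a single
#' stage.
#'
#' @param layers list of layers; each a list with `positive`, `negative`
#'   (character vectors of stage labels) and `name`.
#' @return object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(layers = NULL) {
  if (is.null(layers)) {
    layers <- list(
      list(positive = "AD", negative = c("NC", "EMCI", "LMCI"), name = "AD|rest"),
      list(positive = "NC", negative = c("EMCI", "LMCI"), name = "NC|MCI"),
      list(positive = "EMCI", negative = "LMCI", name = "EMCI|LMCI")
    )
  }
  for (ly in layers) {
    if (length(intersect(ly$positive, ly$negative)) > 0) {
      stop("layer ", ly$name, ": positive and negative sets overlap")
    }
  }
  last <- layers[[length(layers)]]
  if (length(last$positive) != 1 || length(last$negative) != 1) {
    stop("final layer must decide between two single classes")
  }
  structure(layers, class = "hierarchy_spec")
}

#' Train a binary SVM on selected connections
#'
#' Restricts the feature matrix to the edges of a selection mask (falling
#' back to all edges when the mask is empty), z-scores each retained feature
#' with the *training* mean and SD -- so no test statistics ever leak into
#' the fit -- and trains a linear SVM. Constant features get unit scale.
#'
#' @param train_features numeric n x E matrix in the shared edge order.
#' @param train_labels two-level labels (factor/character) or -1/+1.
#' @param mask optional `connection_mask` (or logical vector over edges).
#' @param edges E x 2 edge index (needed to apply an R x R mask).
#' @param C SVM cost (default 1).
#' @return object of class `binary_model` wrapping the SVM, the scaling
#'   statistics and the retained column indices.
#' @export
train_binary <- function(train_features, train_labels, mask = NULL,
                         edges = NULL, C = 1) {
  cols <- seq_len(ncol(train_features))
  if (!is.null(mask)) {
    sel <- if (is.matrix(mask)) {
      if (is.null(edges)) stop("edges required to apply a matrix mask")
      mask[edges]
    } else {
      as.logical(mask)
    }
    if (any(sel)) cols <- which(sel)
  }
  x <- train_features[, cols, drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  model <- linear_svm(xs, train_labels, C = C)
  structure(list(svm = model, center = ctr, scale = scl, cols = cols),
            class = "binary_model")
}

#' @export
predict.binary_model <- function(object, x, type = c("label", "decision"), ...) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xs <- sweep(sweep(x[, object$cols, drop = FALSE], 2, object$center),
              2, object$scale, "/")
  if (type == "decision") svm_decision(object$svm, xs) else
    predict(object$svm, xs)
}

#' Route a subject through a hierarchy of binary models
#'
#' Applies the layer models in order: a positive decision at a layer assigns
#' the layer's (single) positive class and stops; a negative decision at the
#' final layer assigns its negative class. With the default tree: layer 1
#' positive -> AD; else layer 2 positive -> NC; else layer 3 decides EMCI
#' vs LMCI. Exactly one label is always returned.
#'
#' @param models list of `binary_model`s, one per layer, trained with the
#'   layer's positive set as the `+1` class.
#' @param x feature vector (length E) or n x E matrix.
#' @param spec a [hierarchy_spec()].
#' @return character vector of predicted stage labels.
#' @export
predict_hierarchical <- function(models, x, spec = hierarchy_spec()) {
  if (length(models) != length(spec)) {
    stop("need one model per hierarchy layer (", length(spec), "), got ",
         length(models))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- rep(NA_character_, nrow(x))
  todo <- rep(TRUE, nrow(x))
  for (li in seq_along(spec)) {
    if (!any(todo)) break
    if (is.null(models[[li]])) stop("missing model for layer ", spec[[li]]$name)
    d <- predict(models[[li]], x[todo, , drop = FALSE], type = "decision")
    pos <- d >= 0
    idx <- which(todo)
    out[idx[pos]] <- spec[[li]]$positive[1]
    if (li == length(spec)) out[idx[!pos]] <- spec[[li]]$negative[1]
    todo[idx[pos]] <- FALSE
  }
  out
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has ", length(idx), " subjects, fewer than k = ", k,
           "; use a smaller k")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# train the per-layer models of a hierarchy on one training split
fit_hierarchy <- function(x, labels, edges, spec, alpha, C, premask = NULL) {
  lapply(seq_along(spec), function(li) {
    ly <- spec[[li]]
    in_layer <- labels %in% c(ly$positive, ly$negative)
    xl <- x[in_layer, , drop = FALSE]
    yl <- ifelse(labels[in_layer] %in% ly$positive, 1, -1)
    mask <- if (is.null(premask)) {
      pv <- ttest_connections(xl[yl == 1, , drop = FALSE],
                              xl[yl == -1, , drop = FALSE], edges = edges)
      suppressWarnings(select_features(pv, alpha = alpha))
    } else premask[[li]]
    train_binary(xl, yl, mask = mask, edges = edges, C = C)
  })
}

# train one-vs-one machines for the flat scheme on one training split
fit_flat <- function(x, labels, edges, classes, alpha, C, premask = NULL) {
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    in_pair <- labels %in% pr
    xp <- x[in_pair, , drop = FALSE]
    yp <- factor(labels[in_pair], levels = sort(pr))
    mask <- if (is.null(premask)) {
      pv <- ttest_connections(xp[yp == sort(pr)[1], , drop = FALSE],
                              xp[yp == sort(pr)[2], , drop = FALSE],
                              edges = edges)
      suppressWarnings(select_features(pv, alpha = alpha))
    } else premask[[pi]]
    train_binary(xp, yp, mask = mask, edges = edges, C = C)
  })
  list(models = models, pairs = pairs)
}

# one-vs-one voting; ties broken by accumulated decision margin, then by
# stage order
predict_flat <- function(fit, x, classes) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  votes <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  margin <- votes
  for (pi in seq_along(fit$pairs)) {
    pr <- sort(fit$pairs[[pi]])
    d <- predict(fit$models[[pi]], x, type = "decision")
    winner <- ifelse(d >= 0, pr[2], pr[1])
    for (cl in pr) {
      sel <- winner == cl
      votes[sel, cl] <- votes[sel, cl] + 1
      margin[sel, cl] <- margin[sel, cl] + abs(d[sel])
    }
  }
  vapply(seq_len(nrow(x)), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) {
      best <- best[which.max(margin[i, best])]
    }
    classes[best[1]]
  }, character(1))
}

#' Cross-validated flat or hierarchical staging
#'
#' Stratified k-fold cross-validation of the four-stage classifier. Feature
#' selection (per-contrast Welch t-test at `alpha`) and feature z-scoring
#' are refit inside every training fold, so no test-fold statistics leak
#' into training. Predictions from all folds are pooled into a single
#' predicted x ground-truth confusion matrix, and per-fold metrics are
#' reported as mean and SD.
#'
#' @param features a `feature_set`, or an n x E matrix (then give `labels`
#'   and `edges`).
#' @param labels stage labels (NC/EMCI/LMCI/AD), one per subject.
#' @param scheme `"hierarchical"` (default), `"flat"`, or a
#'   [hierarchy_spec()].
#' @param k number of folds (default 10). Every class needs >= k subjects.
#' @param seed fold-assignment seed (default 42).
#' @param alpha edge-selection threshold (default 0.05).
#' @param C SVM cost.
#' @param edges edge index when `features` is a bare matrix.
#' @param paper_mode if `TRUE`, feature selection is computed once on the
#'   full data set before cross-validation (the leaking variant some studies
#'   use); clearly labeled in the result.
#' @return object of class `corrtf_cv`: list with `confusion` (pooled 4x4,
#'   rows = predicted, columns = ground truth), `metrics` (per-fold data
#'   frame plus mean/SD), `scheme`, `seed`, `fold` assignment.
#' @export
crossvalidate <- function(features, labels = NULL, scheme = "hierarchical",
                          k = 10, seed = 42, alpha = 0.05, C = 1,
                          edges = NULL, paper_mode = FALSE) {
  if (inherits(features, "feature_set")) {
    x <- features$x
    labels <- labels %||% features$labels
    edges <- features$edges
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop("labels required")
    if (is.null(edges)) stop("edges required for a bare feature matrix")
  }
  labels <- as.character(labels)
  classes <- stage_levels[stage_levels %in% labels]
  hier <- !identical(scheme, "flat")
  spec <- if (inherits(scheme, "hierarchy_spec")) scheme else
    if (hier) hierarchy_spec() else NULL

  fold <- stratified_folds(labels, k, seed)

  premask <- NULL
  if (paper_mode) {
    premask <- if (hier) {
      lapply(spec, function(ly) {
        pv <- ttest_connections(
          x[labels %in% ly$positive, , drop = FALSE],
          x[labels %in% ly$negative, , drop = FALSE], edges = edges)
        suppressWarnings(select_features(pv, alpha = alpha))
      })
    } else {
      lapply(utils::combn(classes, 2, simplify = FALSE), function(pr) {
        pv <- ttest_connections(x[labels == sort(pr)[1], , drop = FALSE],
                                x[labels == sort(pr)[2], , drop = FALSE],
                                edges = edges)
        suppressWarnings(select_features(pv, alpha = alpha))
      })
    }
  }

  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(predicted = classes, truth = classes))
  fold_rows <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    pred <- if (hier) {
      models <- fit_hierarchy(x[tr, , drop = FALSE], labels[tr], edges, spec,
                              alpha, C, premask)
      predict_hierarchical(models, x[te, , drop = FALSE], spec)
    } else {
      fit <- fit_flat(x[tr, , drop = FALSE], labels[tr], edges, classes,
                      alpha, C, premask)
      predict_flat(fit, x[te, , drop = FALSE], classes)
    }
    truth <- labels[te]
    for (i in seq_along(pred)) cm[pred[i], truth[i]] <- cm[pred[i], truth[i]] + 1L
    cmf <- table(factor(pred, classes), factor(truth, classes))
    mf <- compute_metrics(unclass(as.matrix(cmf)))
    fold_rows[[f]] <- data.frame(fold = f, accuracy = mf$accuracy,
                                 sensitivity = mf$macro["sensitivity"],
                                 specificity = mf$macro["specificity"],
                                 ppv = mf$macro["ppv"], npv = mf$macro["npv"],
                                 row.names = NULL)
  }
  per_fold <- do.call(rbind, fold_rows)
  ms <- colMeans(per_fold[, -1], na.rm = TRUE)
  sds <- apply(per_fold[, -1], 2, sd, na.rm = TRUE)
  structure(list(confusion = cm,
                 metrics = list(per_fold = per_fold, mean = ms, sd = sds),
                 pooled = compute_metrics(cm),
                 scheme = if (hier) "hierarchical" else "flat",
                 k = k, seed = seed, alpha = alpha,
                 paper_mode = paper_mode, fold = fold),
            class = "corrtf_cv")
}

#' @export
print.corrtf_cv <- function(x, ...) {
  cat(sprintf("<corrtf_cv> %s scheme, %d-fold (seed %d)%s\n", x$scheme, x$k,
              x$seed, if (x$paper_mode) " [paper-mode selection: leaks]" else ""))
  cat(sprintf("  pooled accuracy: %.4f\n", x$pooled$accuracy))
  cat(sprintf("  per-fold accuracy: %.4f +/- %.4f\n",
              x$metrics$mean["accuracy"], x$metrics$sd["accuracy"]))
  print(x$confusion)
  invisible(x)
}

#' All pairwise binary cross-validation accuracies
#'
#' Reports the k-fold CV accuracy of a binary SVM for every pair of stages
#' present -- the evidence from which a hierarchy ordering is derived (most
#' separable contrasts classified first).
#'
#' @inheritParams crossvalidate
#' @return data.frame with columns `class_a`, `class_b`, `accuracy`, `sd`.
#' @export
pairwise_binary_cv <- function(features, labels = NULL, k = 10, seed = 42,
                               alpha = 0.05, C = 1) {
  stopifnot(inherits(features, "feature_set"))
  labels <- labels %||% features$labels
  classes <- stage_levels[stage_levels %in% labels]
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    x <- features$x[sel, , drop = FALSE]
    lab <- labels[sel]
    fold <- stratified_folds(lab, k, seed)
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      pv <- ttest_connections(x[tr & lab == pr[1], , drop = FALSE],
                              x[tr & lab == pr[2], , drop = FALSE],
                              edges = features$edges)
      mask <- suppressWarnings(select_features(pv, alpha = alpha))
      m <- train_binary(x[tr, , drop = FALSE], lab[tr], mask = mask,
                        edges = features$edges, C = C)
      mean(predict(m, x[!tr, , drop = FALSE]) == lab[!tr])
    }, numeric(1))
    data.frame(class_a = pr[1], class_b = pr[2],
               accuracy = mean(acc), sd = sd(acc))
  })
  do.call(rbind, rows)
}
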