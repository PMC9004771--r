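#' Linear support vector machine (dual coordinate descent)
#'
#' L2-regularized, L1-loss (hinge) linear SVM solved in the dual by cyclic
#' coordinate descent, the standard large-margin solver for the
#' high-dimensional, small-sample regime of connectivity features. The bias
#' is handled by augmenting each sample with a constant feature, so the
#' optimization is a box-constrained QP:
#' \deqn{\min_\alpha \tfrac12 \alpha^T Q \alpha - e^T \alpha,\quad
#'       0 \le \alpha_i \le C}
#' with \eqn{Q_{ij} = y_i y_j x_i^T x_j}. The solver is deterministic
#' (cyclic update order, no randomization).
#'
#' @param x numeric n x d matrix of training samples.
#' @param y labels in `{-1, +1}` (or a two-level factor, first level mapped
#'   to -1).
#' @param C soft-margin cost (default 1).
#' @param max_pass maximum coordinate-descent sweeps (default 1000).
#' @param tol stop when the largest projected-gradient violation in a sweep
#'   falls below `tol`.
#' @return object of class `linear_svm` with weight vector `w`, bias `b`,
#'   the dual variables `alpha`, and the level mapping when `y` was a factor.
#' @export
linear_svm <- function(x, y, C = 1, max_pass = 1000, tol = 1e-4) {
  x <- as.matrix(x)
  levels_map <- NULL
  if (is.factor(y) || is.character(y)) {
    lv <- unique(as.character(y))
    if (length(lv) == 1) stop("single-class training set")
    if (length(lv) != 2) stop("need exactly two classes, got ", length(lv))
    levels_map <- sort(lv)               # first sorted level -> -1
    y <- ifelse(as.character(y) == levels_map[2], 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1 / +1")
  if (length(unique(y)) < 2) stop("single-class training set")
  n <- nrow(x)
  xa <- cbind(x, 1)                      # augmented bias feature
  qd <- rowSums(xa * xa)
  alpha <- numeric(n)
  w <- numeric(ncol(xa))
  for (pass in seq_len(max_pass)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(xa[i, ] * w) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= C) pg <- max(g, 0)
      if (abs(pg) > 1e-12) {
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / qd[i], 0), C)
        w <- w + (alpha[i] - a_old) * y[i] * xa[i, ]
      }
      max_viol <- max(max_viol, abs(pg))
    }
    if (max_viol < tol) break
  }
  structure(list(w = w[-length(w)], b = w[length(w)], alpha = alpha, C = C,
                 levels = levels_map, passes = pass),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#'
#' @param model a [linear_svm()].
#' @param x numeric matrix (n x d) or vector (length d).
#' @return numeric decision values `x w + b`; positive values vote for the
#'   `+1` class (the second sorted level when the model was fit on a factor).
#' @export
svm_decision <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(x %*% model$w + model$b)
}

#' @export
predict.linear_svm <- function(object, x, ...) {
  d <- svm_decision(object, x)
  if (is.null(object$levels)) {
    ifelse(d >= 0, 1, -1)
  } else {
    ifelse(d >= 0, object$levels[2], object$levels[1])
  }
}
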