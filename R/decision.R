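# Treatment-response decision support: min-max feature scaling, stratified
# cross-validation over the classifier panel (naive Bayes, linear and RBF
# SVM, logistic regression, k-nearest-neighbors with Euclidean or Manhattan
# distance), and 2D Gaussian-naive-Bayes decision surfaces for visualization.

#' Specify a response classifier
#'
#' @param kind One of `"naive_bayes"`, `"linear_svm"`, `"rbf_svm"`,
#'   `"logistic_regression"`, `"knn"`.
#' @param k Neighborhood size (knn only).
#' @param metric `"euclidean"` or `"manhattan"` (knn only).
#' @param seed Seed for classifiers with stochastic fitting.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "naive_bayes", "linear_svm",
                                     "rbf_svm", "logistic_regression"),
                            k = 5L, metric = c("manhattan", "euclidean"),
                            seed = 1L) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  stopifnot(k >= 1L)
  structure(list(kind = kind, k = as.integer(k), metric = metric,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Min-max feature scaling fitted on training data
#'
#' Each column is mapped by `(x - min) / (max - min)` using the training
#' statistics only; values outside the training range are clipped to
#' \[0, 1\], and constant training columns map to 0.
#'
#' @param train Numeric matrix/data frame used to fit the ranges.
#' @param apply_to Data to transform (defaults to `train`).
#' @return List with `scaled` (matrix) and `ranges` (2 x p matrix min/max).
#' @export
minmax_scale <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  stopifnot(nrow(train) >= 1L, ncol(train) == ncol(apply_to))
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  span <- hi - lo
  scaled <- sweep(apply_to, 2, lo)
  scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), `/`)
  scaled[, span == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  list(scaled = scaled, ranges = rbind(min = lo, max = hi))
}

#' Stratified cross-validation folds
#'
#' Assigns every sample to exactly one test fold so that per-fold class
#' proportions deviate from the global proportions by at most one sample:
#' within each class, shuffled members are dealt round-robin across folds.
#'
#' @param labels Vector/factor of class labels.
#' @param k Number of folds (<= number of samples).
#' @param seed Shuffling seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("more folds than samples")
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)   # continue dealing where the last class stopped
  }
  fold
}

# Fit one classifier and return responder-class scores for newdata.
fit_and_score <- function(spec, xtr, ytr, xte) {
  pos <- levels(ytr)[2]
  switch(spec$kind,
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte, type = "raw")[, pos]
    },
    linear_svm = {
      set.seed(spec$seed)
      fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1, probability = FALSE)
      dv <- attr(predict(fit, xte, decision.values = TRUE), "decision.values")
      if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) dv[, 1] else -dv[, 1]
    },
    rbf_svm = {
      set.seed(spec$seed)
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, probability = FALSE)
      dv <- attr(predict(fit, xte, decision.values = TRUE), "decision.values")
      if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) dv[, 1] else -dv[, 1]
    },
    logistic_regression = {
      df <- as.data.frame(xtr); df$.y <- ytr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      suppressWarnings(predict(fit, as.data.frame(xte), type = "response"))
    },
    knn = {
      knn_score(xtr, ytr, xte, k = spec$k, metric = spec$metric, positive = pos)
    })
}

# Distance-weighted k-nearest-neighbor vote fraction for the positive class.
# Implemented directly because the conventional implementations only expose
# Euclidean distances, and the Manhattan variant is a first-class citizen of
# the classifier panel.
knn_score <- function(xtr, ytr, xte, k, metric, positive) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  k <- min(k, nrow(xtr))
  vapply(seq_len(nrow(xte)), function(i) {
    d <- if (metric == "manhattan")
      rowSums(abs(sweep(xtr, 2, xte[i, ])))
    else
      sqrt(rowSums(sweep(xtr, 2, xte[i, ])^2))
    nn <- order(d)[seq_len(k)]
    wgt <- 1 / (d[nn] + 1e-8)
    sum(wgt[ytr[nn] == positive]) / sum(wgt)
  }, 0)
}

#' Stratified cross-validated response classification
#'
#' For each fold: min-max scaling is fitted on the training part only and
#' applied (with clipping) to the test part, the classifier is fitted on the
#' scaled training data, and accuracy plus AUC-ROC are scored on the test
#' part from continuous responder scores (posterior for naive Bayes and
#' logistic regression, decision values for SVMs, distance-weighted vote
#' fraction for knn). Folds containing a single class get no AUC and are
#' excluded from the AUC mean. Rows are sorted canonically before fold
#' construction, so the result is invariant to input row order.
#'
#' @param features Numeric matrix/data frame (rows = samples).
#' @param labels Two-level factor (second level = positive class) or a
#'   vector coercible to one.
#' @param spec A [classifier_spec()].
#' @param k Number of folds.
#' @param seed Fold-shuffling seed.
#' @return Object of class `cv_result`: `per_fold` data frame (`fold`,
#'   `accuracy`, `auc`), `mean_accuracy`, `mean_auc`, `fold_assignments`.
#' @export
cross_validate <- function(features, labels, spec = classifier_spec(),
                           k = 10L, seed = 1L) {
  x <- as.matrix(features)
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("need exactly 2 classes")
  ord <- do.call(order, c(as.data.frame(x), list(as.integer(labels))))
  x <- x[ord, , drop = FALSE]; labels <- labels[ord]
  folds <- stratified_folds(labels, k = k, seed = seed)
  per <- data.frame(fold = seq_len(k), accuracy = NA_real_, auc = NA_real_)
  pos <- levels(labels)[2]
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    sc <- minmax_scale(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    xtr <- minmax_scale(x[tr, , drop = FALSE])$scaled
    scores <- fit_and_score(spec, xtr, labels[tr], sc$scaled)
    pred <- ifelse(scores > score_cut(spec), pos, levels(labels)[1])
    per$accuracy[f] <- mean(pred == as.character(labels[te]))
    if (length(unique(labels[te])) == 2L) {
      per$auc[f] <- as.numeric(pROC::auc(pROC::roc(
        response = labels[te], predictor = as.numeric(scores),
        levels = levels(labels), direction = "<", quiet = TRUE)))
    }
  }
  structure(list(per_fold = per,
                 mean_accuracy = mean(per$accuracy),
                 mean_auc = mean(per$auc, na.rm = TRUE),
                 fold_assignments = folds[order(ord)],
                 spec = spec, k = k, seed = seed),
            class = "cv_result")
}

score_cut <- function(spec) {
  if (spec$kind %in% c("linear_svm", "rbf_svm")) 0 else 0.5
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV, %s: accuracy %.1f%%, AUC-ROC %.1f%%\n",
              x$k, x$spec$kind, 100 * x$mean_accuracy, 100 * x$mean_auc))
  invisible(x)
}

#' Majority-class baseline accuracy ("educated guess")
#'
#' Predicts the training majority class for every test sample, under the
#' same stratified folds; score ties fall back to the class prior.
#'
#' @inheritParams cross_validate
#' @return A `cv_result` with constant scores (AUC 0.5 by construction).
#' @export
educated_guess_cv <- function(labels, k = 10L, seed = 1L) {
  if (!is.factor(labels)) labels <- factor(labels)
  folds <- stratified_folds(labels, k = k, seed = seed)
  per <- data.frame(fold = seq_len(k), accuracy = NA_real_, auc = 0.5)
  for (f in seq_len(k)) {
    maj <- names(which.max(table(labels[folds != f])))
    per$accuracy[f] <- mean(labels[folds == f] == maj)
  }
  structure(list(per_fold = per, mean_accuracy = mean(per$accuracy),
                 mean_auc = 0.5, fold_assignments = folds,
                 spec = list(kind = "educated_guess"), k = k, seed = seed),
            class = "cv_result")
}

#' Gaussian naive Bayes posterior surface over a 2D feature grid
#'
#' Fits a Gaussian naive Bayes model on two (scaled) feature columns and
#' evaluates the responder-class posterior on a regular grid spanning the
#' feature range — the background shading used to visualize decision
#' boundaries in 2D feature subspaces.
#'
#' @param features Matrix/data frame with exactly 2 columns.
#' @param labels Two-level factor (second level = positive/responder).
#' @param resolution Grid points per axis.
#' @param expand Fractional range expansion beyond the data extent.
#' @return List with `x`, `y` (axis vectors) and `posterior`
#'   (resolution x resolution matrix in \[0,1\], responder class).
#' @export
nb_decision_surface <- function(features, labels, resolution = 101L,
                                expand = 0.05) {
  x <- as.matrix(features)
  stopifnot(ncol(x) == 2L)
  if (!is.factor(labels)) labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  pos <- levels(labels)[2]
  pad <- function(v) {
    r <- range(v); d <- diff(r)
    seq(r[1] - expand * d, r[2] + expand * d, length.out = resolution)
  }
  gx <- pad(x[, 1]); gy <- pad(x[, 2])
  # Gaussian class likelihoods with per-class, per-feature mean and variance
  stats_of <- function(cl) {
    xs <- x[labels == cl, , drop = FALSE]
    list(mu = colMeans(xs), s2 = pmax(apply(xs, 2, var), 1e-12),
         prior = mean(labels == cl))
  }
  st <- lapply(levels(labels), stats_of)
  names(st) <- levels(labels)
  grid <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  loglik <- function(s) {
    -0.5 * ((grid[, 1] - s$mu[1])^2 / s$s2[1] + (grid[, 2] - s$mu[2])^2 / s$s2[2]) -
      0.5 * log(2 * pi * s$s2[1]) - 0.5 * log(2 * pi * s$s2[2]) + log(s$prior)
  }
  l1 <- loglik(st[[1]]); l2 <- loglik(st[[2]])
  m <- pmax(l1, l2)
  p2 <- exp(l2 - m) / (exp(l1 - m) + exp(l2 - m))
  post <- matrix(p2, resolution, resolution)  # rows follow gx, cols gy
  list(x = gx, y = gy, posterior = post, positive = pos)
}
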