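# Classical texture-feature baseline: statistical RGB moments, grey-level
# co-occurrence features, local binary patterns and Tamura texture features,
# fed to a conventional patch classifier (RBF-SVM or random forest). Serves
# as the reference the segmentation network is benchmarked against on the
# synthetic data.

#' Texture feature configuration
#'
#' @param n_levels Grey levels for co-occurrence quantization (intensity in
#'   \[0,1\] is binned uniformly).
#' @param offsets List of (drow, dcol) co-occurrence offsets; features are
#'   averaged over offsets and the matrices are symmetrized.
#' @param lbp_mapping `"u2"` (58 uniform patterns + 1 other) or `"riu2"`
#'   (rotation-invariant uniform: 10 bins).
#' @param tamura_max_k Largest coarseness scale exponent (window `2^k`).
#' @return Object of class `texture_config`.
#' @export
texture_config <- function(n_levels = 32L,
                           offsets = list(c(0L, 1L), c(1L, 0L),
                                          c(1L, 1L), c(1L, -1L)),
                           lbp_mapping = c("u2", "riu2"),
                           tamura_max_k = 5L) {
  structure(list(n_levels = as.integer(n_levels), offsets = offsets,
                 lbp_mapping = match.arg(lbp_mapping),
                 tamura_max_k = as.integer(tamura_max_k)),
            class = "texture_config")
}

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized grey levels at the given offset,
#' symmetrized (both directions) and normalized to sum 1.
#'
#' @param grey Numeric matrix in \[0,1\].
#' @param offset Integer (drow, dcol).
#' @param n_levels Number of quantization levels.
#' @param normalize Divide by the total count (set `FALSE` for raw tallies).
#' @return n_levels x n_levels matrix.
#' @export
glcm <- function(grey, offset, n_levels = 32L, normalize = TRUE) {
  q <- pmin(floor(grey * n_levels), n_levels - 1L)
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  a <- q[r1, c1]
  b <- q[r1 + dr, c1 + dc]
  m <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = 0:(n_levels - 1L)),
               factor(b, levels = 0:(n_levels - 1L)))
  m <- m + tab + t(tab)
  if (normalize && sum(m) > 0) m <- m / sum(m)
  unclass(as.matrix(m))
}

glcm_features <- function(grey, config) {
  feats <- sapply(config$offsets, function(off) {
    p <- glcm(grey, off, config$n_levels)
    lev <- seq_len(nrow(p)) - 1L
    di <- outer(lev, lev, `-`)
    mu_i <- sum(rowSums(p) * lev)
    mu_j <- sum(colSums(p) * lev)
    s_i <- sqrt(sum(rowSums(p) * (lev - mu_i)^2))
    s_j <- sqrt(sum(colSums(p) * (lev - mu_j)^2))
    corr <- if (s_i < 1e-12 || s_j < 1e-12) 1
    else sum(p * outer(lev - mu_i, lev - mu_j)) / (s_i * s_j)
    c(contrast = sum(p * di^2),
      correlation = corr,
      energy = sum(p^2),
      homogeneity = sum(p / (1 + di^2)))
  })
  rowMeans(feats)
}

lbp_histogram <- function(grey, mapping) {
  h <- nrow(grey); w <- ncol(grey)
  ctr <- grey[2:(h - 1), 2:(w - 1)]
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  code <- matrix(0L, h - 2, w - 2)
  bits <- vector("list", 8)
  for (k in 1:8) {
    o <- offs[[k]]
    nb <- grey[2:(h - 1) + o[1], 2:(w - 1) + o[2]]
    bits[[k]] <- nb >= ctr
    code <- code + as.integer(bits[[k]]) * 2L^(k - 1L)
  }
  transitions <- function(v) {  # bit transitions in the circular 8-bit code
    b <- as.integer(intToBits(v))[1:8]
    sum(b != c(b[-1], b[1]))
  }
  codes <- 0:255
  tr <- vapply(codes, transitions, 0L)
  ones <- vapply(codes, function(v) sum(as.integer(intToBits(v))[1:8]), 0L)
  if (mapping == "riu2") {
    bin <- ifelse(tr <= 2L, ones, 9L)          # 0..8 uniform, 9 = other
    nb <- 10L
  } else {
    bin <- integer(256)
    bin[tr <= 2L] <- seq_len(sum(tr <= 2L)) - 1L
    bin[tr > 2L] <- sum(tr <= 2L)              # 58 uniform + 1 other
    nb <- sum(tr <= 2L) + 1L
  }
  hist <- tabulate(bin[code + 1L] + 1L, nbins = nb)
  hist / sum(hist)
}

tamura_features <- function(grey, max_k) {
  h <- nrow(grey); w <- ncol(grey)
  # coarseness: per pixel, the window size 2^k with the largest mean
  # difference between opposite neighborhoods, averaged
  box_mean <- function(k) {
    s <- 2L^k
    cm <- apply(grey, 2, cumsum); cm <- rbind(0, cm)
    cm2 <- t(apply(cm, 1, cumsum)); cm2 <- cbind(0, cm2)
    out <- matrix(NA_real_, h, w)
    r0 <- pmax(1L, seq_len(h) - s %/% 2L); r1 <- pmin(h, r0 + s - 1L)
    c0 <- pmax(1L, seq_len(w) - s %/% 2L); c1 <- pmin(w, c0 + s - 1L)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      out[i, j] <- (cm2[r1[i] + 1L, c1[j] + 1L] - cm2[r0[i], c1[j] + 1L] -
                      cm2[r1[i] + 1L, c0[j]] + cm2[r0[i], c0[j]]) /
        ((r1[i] - r0[i] + 1L) * (c1[j] - c0[j] + 1L))
    }
    out
  }
  ks <- seq_len(min(max_k, floor(log2(min(h, w) / 2))))
  best_e <- matrix(-Inf, h, w); best_s <- matrix(1, h, w)
  for (k in ks) {
    s <- 2L^(k - 1L)
    A <- box_mean(k)
    shift <- function(m, dr, dc) {
      ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
      ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
      m[ri, ci]
    }
    e <- pmax(abs(shift(A, s, 0) - shift(A, -s, 0)),
              abs(shift(A, 0, s) - shift(A, 0, -s)))
    upd <- e > best_e
    best_e[upd] <- e[upd]; best_s[upd] <- 2^k
  }
  coarseness <- mean(best_s)
  # contrast: sd / kurtosis^(1/4)
  s <- sd(as.vector(grey))
  contrast <- if (s < 1e-12) 0 else {
    m4 <- mean((grey - mean(grey))^4)
    s / (m4 / s^4)^(1 / 4)
  }
  # directionality: peakness of the gradient-orientation histogram
  gh <- grey[, c(2:w, w)] - grey[, c(1, 1:(w - 1))]
  gv <- grey[c(2:h, h), ] - grey[c(1, 1:(h - 1)), ]
  mag <- sqrt(gh^2 + gv^2)
  strong <- mag > 0.05 * max(mag, 1e-12)
  directionality <- if (!any(strong)) 0 else {
    theta <- atan2(gv[strong], gh[strong]) %% pi
    nb <- 16L
    hst <- tabulate(pmin(floor(theta / pi * nb), nb - 1L) + 1L, nbins = nb)
    hst <- hst / sum(hst)
    pk <- which.max(hst)
    circ <- (seq_len(nb) - pk + nb / 2) %% nb - nb / 2   # signed circular bin distance
    ang <- circ / nb * pi                                # radians in [-pi/2, pi/2)
    1 - sum(hst * ang^2) / (pi / 2)^2
  }
  c(coarseness = coarseness, contrast = contrast, directionality = directionality)
}

#' Hand-crafted texture feature vector of one RGB patch
#'
#' Concatenates per-channel RGB moments (mean, standard deviation, skewness),
#' grey-level co-occurrence features (contrast, correlation, energy,
#' homogeneity, averaged over the configured offsets), the normalized local
#' binary pattern histogram (radius 1, 8 points, uniform mapping), and Tamura
#' coarseness, contrast and directionality.
#'
#' @param patch H x W x 3 RGB array, at least 8 x 8.
#' @param config A [texture_config()].
#' @return Named numeric vector of fixed length for a given configuration.
#' @export
texture_features <- function(patch, config = texture_config()) {
  d <- dim(patch)
  if (d[1] < 8L || d[2] < 8L) stop("patch too small for the texture operators")
  moms <- unlist(lapply(1:3, function(ch) {
    v <- as.vector(patch[, , ch])
    s <- sd(v)
    skew <- if (s < 1e-12) 0 else mean((v - mean(v))^3) / s^3
    c(mean = mean(v), sd = s, skew = skew)
  }))
  names(moms) <- paste0("mom_", c("r", "g", "b"), rep(c("_mean", "_sd", "_skew"), times = 0) )
  names(moms) <- as.vector(t(outer(c("r", "g", "b"),
                                   c("mean", "sd", "skew"), paste, sep = "_")))
  names(moms) <- paste0("mom_", names(moms))
  grey <- luminance(patch)
  gl <- glcm_features(grey, config)
  names(gl) <- paste0("glcm_", names(gl))
  lbp <- lbp_histogram(grey, config$lbp_mapping)
  names(lbp) <- paste0("lbp_", seq_along(lbp))
  tam <- tamura_features(grey, config$tamura_max_k)
  names(tam) <- paste0("tamura_", names(tam))
  c(moms, gl, lbp, tam)
}

#' Sample balanced single-class patches from annotated tiles
#'
#' Scans a non-overlapping grid over every tile and keeps patches whose
#' annotation is a single class, then subsamples so every class present
#' contributes equally (capped by the rarest class and `per_class`). Classes
#' without any pure patch are excluded with a warning.
#'
#' @param dataset List of samples with `image` and `annotation`.
#' @param patch_size Patch side in pixels.
#' @param per_class Upper bound of patches kept per class.
#' @param seed Sampling seed.
#' @return List with `patches` (list of arrays) and `labels` (integer ids).
#' @export
sample_class_patches <- function(dataset, patch_size = 16L, per_class = 50L,
                                 seed = 1L) {
  set.seed(seed)
  patches <- list(); labels <- integer(0)
  for (s in dataset) {
    d <- dim(s$annotation)
    for (r0 in seq(0L, d[1] - patch_size, by = patch_size)) {
      for (c0 in seq(0L, d[2] - patch_size, by = patch_size)) {
        ann <- s$annotation[r0 + seq_len(patch_size), c0 + seq_len(patch_size)]
        u <- unique(as.vector(ann))
        if (length(u) == 1L) {
          patches[[length(patches) + 1L]] <-
            s$image[r0 + seq_len(patch_size), c0 + seq_len(patch_size), , drop = FALSE]
          labels <- c(labels, u)
        }
      }
    }
  }
  if (!length(labels)) stop("no pure-class patches found; reduce patch_size")
  counts <- table(labels)
  cap <- min(min(counts), per_class)
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == as.integer(cl))
    idx[sample.int(length(idx), cap)]
  }))
  missing <- setdiff(0:7, as.integer(names(counts)))
  if (length(missing))
    warning("classes without pure patches excluded: ", paste(missing, collapse = ", "))
  list(patches = patches[keep], labels = labels[keep])
}

#' Cross-validated patch classification with the texture baseline
#'
#' Balanced single-class patches are described by [texture_features()] and
#' classified with an RBF-SVM or random forest under stratified k-fold CV.
#'
#' @param dataset List of samples with `image` and `annotation`.
#' @param classifier `"rbf_svm"` or `"random_forest"`.
#' @param folds Number of CV folds.
#' @param seed Seed for sampling, folds and the forest.
#' @param patch_size,per_class Passed to [sample_class_patches()].
#' @param config A [texture_config()].
#' @return List with `per_fold` (precision, recall, weighted and macro F1),
#'   `mean_f1` (weighted), `mean_macro_f1`, and the fitted-on-all-data
#'   `fit`, `config`, `patch_size` for reuse as a patchwise segmenter.
#' @export
baseline_cv <- function(dataset, classifier = c("rbf_svm", "random_forest"),
                        folds = 5L, seed = 1L, patch_size = 16L,
                        per_class = 50L, config = texture_config()) {
  classifier <- match.arg(classifier)
  smp <- sample_class_patches(dataset, patch_size, per_class, seed)
  feats <- t(vapply(smp$patches, texture_features,
                    texture_features(smp$patches[[1]], config), config = config))
  y <- factor(smp$labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  fold <- stratified_folds(y, k = folds, seed = seed)
  per <- data.frame(fold = seq_len(folds), precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, macro_f1 = NA_real_)
  fit_one <- function(xtr, ytr) {
    set.seed(seed)
    if (classifier == "rbf_svm") e1071::svm(xtr, ytr, kernel = "radial", cost = 1)
    else randomForest::randomForest(xtr, ytr)
  }
  for (f in seq_len(folds)) {
    tr <- fold != f
    sc <- minmax_scale(feats[tr, , drop = FALSE], feats[!tr, , drop = FALSE])
    fit <- fit_one(minmax_scale(feats[tr, , drop = FALSE])$scaled, y[tr])
    pred <- predict(fit, sc$scaled)
    m <- class_metrics(as.integer(as.character(pred)),
                       as.integer(as.character(y[!tr])))
    per[f, 2:5] <- m
  }
  sc_all <- minmax_scale(feats)
  fit_all <- fit_one(sc_all$scaled, y)
  list(per_fold = per,
       mean_f1 = mean(per$f1), mean_macro_f1 = mean(per$macro_f1),
       fit = fit_all, ranges = sc_all$ranges, config = config,
       patch_size = patch_size, classifier = classifier)
}

class_metrics <- function(pred, truth) {
  cls <- sort(unique(truth))
  stats <- t(vapply(cls, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1, sum(truth == cl))
  }, numeric(4)))
  wts <- stats[, 4] / sum(stats[, 4])
  c(precision = sum(stats[, 1] * wts), recall = sum(stats[, 2] * wts),
    f1 = sum(stats[, 3] * wts), macro_f1 = mean(stats[, 3]))
}

#' Patchwise segmentation with a fitted texture baseline
#'
#' Applies the baseline classifier over a non-overlapping grid and paints
#' each block with its predicted class — the patchwise analogue of semantic
#' segmentation, with spatial resolution limited to the patch size.
#'
#' @param baseline Result of [baseline_cv()].
#' @param image H x W x 3 RGB array (dims multiples of the patch size).
#' @return Integer H x W label matrix.
#' @export
baseline_predict_map <- function(baseline, image) {
  ps <- baseline$patch_size
  d <- dim(image)
  out <- matrix(0L, d[1], d[2])
  for (r0 in seq(0L, d[1] - ps, by = ps)) {
    for (c0 in seq(0L, d[2] - ps, by = ps)) {
      patch <- image[r0 + seq_len(ps), c0 + seq_len(ps), , drop = FALSE]
      fv <- matrix(texture_features(patch, baseline$config), nrow = 1)
      lo <- baseline$ranges["min", ]; hi <- baseline$ranges["max", ]
      span <- hi - lo
      fv <- pmin(pmax((fv - lo) / ifelse(span > 0, span, 1), 0), 1)
      fv[, span == 0] <- 0
      colnames(fv) <- colnames(baseline$ranges)
      pred <- predict(baseline$fit, fv)
      out[r0 + seq_len(ps), c0 + seq_len(ps)] <- as.integer(as.character(pred))
    }
  }
  out
}
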