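# Whole-image inference: foreground selection, 25%-overlap grid tiling,
# Monte-Carlo-dropout sampling of mean/variance probability maps, tent-window
# merging of overlapping tiles, argmax labeling, and class-color rendering.

#' Tissue foreground mask
#'
#' Otsu threshold on luminance (tissue is darker than the white slide
#' background) followed by removal of connected foreground components smaller
#' than `min_size` pixels.
#'
#' @param image H x W x 3 RGB array.
#' @param min_size Minimum connected-component area kept, in pixels.
#' @return Logical H x W matrix, TRUE on tissue.
#' @export
foreground_mask <- function(image, min_size = 64L) {
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (max(lum) - min(lum) < 1e-6) return(matrix(FALSE, nrow(lum), ncol(lum)))
  thr <- EBImage::otsu(EBImage::Image(lum), range = range(lum))
  mask <- lum < thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which(sizes >= min_size)
  matrix(as.integer(EBImage::imageData(lab)) %in% keep, nrow(lum), ncol(lum))
}

#' Overlapping tile grid
#'
#' Square tiles of side `patch_size` on a regular grid with stride
#' `round(patch_size * (1 - overlap_fraction))`; the last tile per axis is
#' clamped so it ends exactly at the image border, so the union of tiles
#' covers every pixel. Coordinates are 0-based, half-open.
#'
#' @param height,width Image extent in pixels.
#' @param patch_size Tile side, <= min(height, width).
#' @param overlap_fraction Fractional overlap between neighboring tiles
#'   (default 0.25).
#' @return Data frame with columns `row0`, `col0`, `height`, `width`.
#' @export
tile_grid <- function(height, width, patch_size, overlap_fraction = 0.25) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  if (patch_size > min(height, width))
    stop("patch_size exceeds the image extent")
  stride <- max(1L, round(patch_size * (1 - overlap_fraction)))
  starts <- function(n) {
    s <- seq(0L, max(0L, n - patch_size), by = stride)
    if (s[length(s)] + patch_size < n) s <- c(s, n - patch_size)
    unique(pmin(s, n - patch_size))
  }
  g <- expand.grid(row0 = starts(height), col0 = starts(width))
  g$height <- as.integer(patch_size)
  g$width <- as.integer(patch_size)
  g[order(g$row0, g$col0), , drop = FALSE]
}

#' Monte-Carlo-dropout mean and variance maps for one patch
#'
#' Runs `n_samples` stochastic forward passes (Alpha-Dropout active; sample k
#' uses `seed + k`) and reduces them to a per-pixel per-class mean probability
#' map and variance map (population variance across samples). With one sample,
#' or a dropout-free model, the variance is identically zero.
#'
#' @param model A trained `histonet` model.
#' @param patch H x W x 3 RGB array.
#' @param n_samples Number of stochastic passes (>= 1); 5 by default.
#' @param seed Base seed for the sample fan-out.
#' @param return_samples Keep the individual sample maps (for diagnostics).
#' @return List with `mean` and `var` (H x W x 8 arrays), `dist` (mean
#'   distribution-head output) and optionally `samples`.
#' @export
predict_stochastic <- function(model, patch, n_samples = 5L, seed = 1L,
                               return_samples = FALSE) {
  stopifnot(n_samples >= 1L)
  d <- dim(patch)
  acc <- array(0, c(d[1], d[2], model$config$n_classes))
  acc2 <- acc
  dist <- numeric(model$config$n_classes)
  samples <- if (return_samples) vector("list", n_samples) else NULL
  for (k in seq_len(n_samples)) {
    out <- net_forward(model, patch, stochastic = TRUE, seed = seed + k)
    acc <- acc + out$prob
    acc2 <- acc2 + out$prob^2
    dist <- dist + out$dist
    if (return_samples) samples[[k]] <- out$prob
  }
  m <- acc / n_samples
  v <- pmax(acc2 / n_samples - m^2, 0)
  v[v < 1e-12] <- 0   # snap accumulation dust so deterministic passes give exact zeros
  list(mean = m, var = v, dist = dist / n_samples, samples = samples)
}

# Separable triangular blend weights for one grid axis. Each tile gets a raw
# tent (weight grows linearly with the distance to its nearer edge); the raw
# tents of all tiles covering a position are then normalized to sum to 1, so
# the per-axis weights form an exact partition of unity for any grid,
# including clamped border tiles and overlaps beyond 50%.
axis_weights <- function(starts, patch, total) {
  m <- length(starts)
  raw <- matrix(0, m, total)
  for (i in seq_len(m)) {
    x <- starts[i] + seq_len(patch)
    raw[i, x] <- pmin(x - starts[i], starts[i] + patch + 1 - x)
  }
  colsum <- colSums(raw)
  if (any(colsum <= 0)) stop("tile boxes do not cover the image")
  sweep(raw, 2, colsum, `/`)
}

#' Merge per-tile prediction maps into a full-image map
#'
#' Each tile is weighted by a separable triangular window (the bilinear blend
#' across tile overlaps); windows are flattened at image borders so the
#' weights over all tiles covering a pixel sum to exactly 1. Merging is
#' therefore a convex combination per pixel, and merged mean maps stay on the
#' probability simplex.
#'
#' @param tiles List of per-tile results, each with `mean` and `var` arrays
#'   matching the corresponding box.
#' @param boxes Tile boxes from [tile_grid()] (rows aligned with `tiles`).
#' @param shape Full-image (height, width).
#' @return List with full-image `mean` and `var` (H x W x 8) arrays.
#' @export
merge_tiles <- function(tiles, boxes, shape) {
  stopifnot(length(tiles) == nrow(boxes))
  h <- shape[1]; w <- shape[2]
  nc <- dim(tiles[[1]]$mean)[3]
  patch_r <- boxes$height[1]; patch_c <- boxes$width[1]
  wr_all <- axis_weights(sort(unique(boxes$row0)), patch_r, h)
  wc_all <- axis_weights(sort(unique(boxes$col0)), patch_c, w)
  r_idx <- match(boxes$row0, sort(unique(boxes$row0)))
  c_idx <- match(boxes$col0, sort(unique(boxes$col0)))
  mean_acc <- array(0, c(h, w, nc))
  var_acc <- array(0, c(h, w, nc))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    ri <- b$row0 + seq_len(b$height)
    ci <- b$col0 + seq_len(b$width)
    wmat <- outer(wr_all[r_idx[i], ri], wc_all[c_idx[i], ci])
    for (c in seq_len(nc)) {
      mean_acc[ri, ci, c] <- mean_acc[ri, ci, c] + wmat * tiles[[i]]$mean[, , c]
      var_acc[ri, ci, c] <- var_acc[ri, ci, c] + wmat * tiles[[i]]$var[, , c]
    }
  }
  list(mean = mean_acc, var = var_acc)
}

# Blend weight field of a tile grid: the per-pixel sum of all tile windows
# (exposed so the partition of unity is directly testable).
tile_weight_field <- function(boxes, shape) {
  h <- shape[1]; w <- shape[2]
  wr_all <- axis_weights(sort(unique(boxes$row0)), boxes$height[1], h)
  wc_all <- axis_weights(sort(unique(boxes$col0)), boxes$width[1], w)
  r_idx <- match(boxes$row0, sort(unique(boxes$row0)))
  c_idx <- match(boxes$col0, sort(unique(boxes$col0)))
  wsum <- matrix(0, h, w)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    ri <- b$row0 + seq_len(b$height); ci <- b$col0 + seq_len(b$width)
    wsum[ri, ci] <- wsum[ri, ci] + outer(wr_all[r_idx[i], ri], wc_all[c_idx[i], ci])
  }
  wsum
}

#' Per-pixel argmax labels of a probability map
#'
#' Ties break toward the lowest class id.
#'
#' @param mean H x W x 8 probability array.
#' @return Integer H x W matrix of label ids 0..7.
#' @export
argmax_labels <- function(mean) {
  d <- dim(mean)
  m <- matrix(mean, ncol = d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Render label maps and variance maps in class colors
#'
#' `render_labels` paints each pixel with its class display color.
#' `render_variance` sums the per-class variances weighted by the class
#' colors and normalizes the result by its maximum channel value (an all-zero
#' variance renders black). Channel *ratios* are invariant to this global
#' normalization, which is what the downstream correction rule relies on.
#'
#' @param labels Integer label matrix.
#' @param variance H x W x 8 per-class variance array.
#' @param palette A [make_palette()].
#' @return H x W x 3 RGB array in \[0,1\].
#' @export
render_labels <- function(labels, palette = make_palette()) {
  stopifnot_labels(labels)
  cols <- palette_colors(palette)
  array(cols[as.vector(labels) + 1L, ], c(dim(labels), 3L))
}

#' @rdname render_labels
#' @export
render_variance <- function(variance, palette = make_palette()) {
  d <- dim(variance)
  cols <- palette_colors(palette)
  rgb <- matrix(variance, ncol = d[3]) %*% cols
  mx <- max(rgb)
  if (mx > 0) rgb <- rgb / mx
  array(rgb, c(d[1], d[2], 3L))
}

#' Segment a whole image with a fitted model
#'
#' The full prediction pipeline: overlapping grid tiling (25% by default),
#' `samples` stochastic dropout passes per tile, tent-window merging into
#' full-image mean and variance probability maps, argmax labeling, and
#' optional automated correction of the blood-cell/necrosis confusion from
#' the variance rendering.
#'
#' @param object A trained `histonet` model.
#' @param image H x W x 3 RGB array; dims must be multiples of `2^levels`.
#' @param patch_size Tile side (default 64; must divide by `2^levels`).
#' @param overlap Fractional tile overlap.
#' @param samples Stochastic samples per tile (5 by default).
#' @param seed Base seed for the stochastic passes.
#' @param correct Apply [correct_blc_nec()] to the argmax labels.
#' @param ... Unused.
#' @return Object of class `histonet_prediction`: list with `mean`, `var`
#'   (H x W x 8), `labels` (argmax map, corrected if requested),
#'   `labels_raw`, `variance_rgb` and `tissue_rgb`.
#' @export
predict.histonet <- function(object, image, patch_size = 64L, overlap = 0.25,
                             samples = 5L, seed = 1L, correct = TRUE, ...) {
  if (!object$trained) warning("predicting with an untrained model")
  d <- dim(image)
  boxes <- tile_grid(d[1], d[2], patch_size, overlap)
  tiles <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    patch <- image[b$row0 + seq_len(b$height), b$col0 + seq_len(b$width), , drop = FALSE]
    tiles[[i]] <- predict_stochastic(object, patch, n_samples = samples,
                                     seed = seed + (i - 1L) * (samples + 1L))
  }
  merged <- merge_tiles(tiles, boxes, d[1:2])
  labels_raw <- argmax_labels(merged$mean)
  vrgb <- render_variance(merged$var, object$palette)
  labels <- if (correct) correct_blc_nec(labels_raw, vrgb) else labels_raw
  structure(list(mean = merged$mean, var = merged$var,
                 labels = labels, labels_raw = labels_raw,
                 variance_rgb = vrgb,
                 tissue_rgb = render_labels(labels, object$palette)),
            class = "histonet_prediction")
}

#' @export
print.histonet_prediction <- function(x, ...) {
  d <- dim(x$labels)
  f <- true_distribution(x$labels)
  pal <- make_palette()
  cat(sprintf("tissue prediction %d x %d px\n", d[1], d[2]))
  top <- order(f, decreasing = TRUE)
  for (i in top[f[top] > 0])
    cat(sprintf("  %s: %.1f%%\n", pal$name[i], 100 * f[i]))
  invisible(x)
}
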