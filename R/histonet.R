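# The segmentation network: an encoder of strided reduce blocks (with Alpha
# Dropout) and residual bottleneck blocks (1x1 compress -> 3x3 convolve -> 1x1
# expand, residual add, SELU), a semantic head that compresses every feature
# level with 1x1 convolutions, upsamples bilinearly to input resolution,
# concatenates and classifies per pixel, and an auxiliary head predicting the
# patch-level tissue distribution from globally pooled deep features. Trained
# with the three-term loss CCE + DDL + MSE.

#' Network architecture configuration
#'
#' @param levels Number of strided reduction stages (spatial size halves per
#'   stage; inputs must be divisible by `2^levels`).
#' @param base_width Channels after the first reduction; doubles per level.
#' @param bottleneck_factor Channel compression inside residual blocks (the
#'   3x3 convolution runs at `width / bottleneck_factor` channels).
#' @param blocks_per_level Residual bottleneck blocks per level.
#' @param compression_widths Per-level channel counts of the semantic head's
#'   1x1 compressions (length `levels`).
#' @param dropout_rate Alpha-Dropout rate in the reduce blocks, in \[0, 1).
#' @param n_classes Number of output classes (8 for the tissue schema).
#' @param in_channels Input channels (3 for RGB).
#' @param seed Seed for weight initialization.
#' @return Object of class `histonet_config`.
#' @export
net_config <- function(levels = 4L, base_width = 32L, bottleneck_factor = 4L,
                       blocks_per_level = 2L,
                       compression_widths = c(8L, 12L, 16L, 24L),
                       dropout_rate = 0.1, n_classes = 8L, in_channels = 3L,
                       seed = 1L) {
  stopifnot(levels >= 2L, base_width >= 1L, bottleneck_factor >= 1L,
            blocks_per_level >= 1L,
            length(compression_widths) == levels,
            all(compression_widths >= 1L),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(levels = as.integer(levels),
                 base_width = as.integer(base_width),
                 bottleneck_factor = as.integer(bottleneck_factor),
                 blocks_per_level = as.integer(blocks_per_level),
                 compression_widths = as.integer(compression_widths),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "histonet_config")
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate `5e-4` and
#' weight decay `1e-6` (applied as an L2 term added to the gradient).
#'
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay L2 weight decay (>= 0).
#' @param epochs Training epochs.
#' @param seed Seed controlling shuffling, augmentation and dropout.
#' @param augment Apply random flips, 90-degree rotations, integer
#'   translations and stain shifts per iteration.
#' @param stain_magnitude Stain-augmentation magnitude in standard deviations
#'   of the fitted principal color basis.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-6,
                         epochs = 10L, seed = 1L, augment = TRUE,
                         stain_magnitude = 0.5) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, epochs >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment = isTRUE(augment), stain_magnitude = stain_magnitude),
            class = "train_config")
}

level_widths <- function(config) config$base_width * 2L^(seq_len(config$levels) - 1L)

#' Build an untrained segmentation model
#'
#' Initializes all weights with LeCun-normal draws (`sd = 1/sqrt(fan_in)`),
#' the initialization under which SELU activations self-normalize. The same
#' config (including its seed) always yields identical initial weights.
#'
#' @param config A [net_config()].
#' @return Object of class `histonet` with `trained = FALSE`.
#' @export
build_model <- function(config = net_config()) {
  stopifnot(inherits(config, "histonet_config"))
  set.seed(config$seed)
  lecun <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, 1 / sqrt(fan_in)), nr, nc)
  widths <- level_widths(config)
  params <- list()
  cin <- config$in_channels
  for (l in seq_len(config$levels)) {
    cl <- widths[l]
    params[[sprintf("reduce%d_W", l)]] <- lecun(9L * cin, cl, 9L * cin)
    params[[sprintf("reduce%d_b", l)]] <- numeric(cl)
    cb <- max(1L, cl %/% config$bottleneck_factor)
    for (m in seq_len(config$blocks_per_level)) {
      p <- sprintf("block%d_%d", l, m)
      params[[paste0(p, "_W1")]] <- lecun(cl, cb, cl)
      params[[paste0(p, "_b1")]] <- numeric(cb)
      params[[paste0(p, "_W2")]] <- lecun(9L * cb, cb, 9L * cb)
      params[[paste0(p, "_b2")]] <- numeric(cb)
      params[[paste0(p, "_W3")]] <- lecun(cb, cl, cb)
      params[[paste0(p, "_b3")]] <- numeric(cl)
    }
    params[[sprintf("comp%d_W", l)]] <- lecun(cl, config$compression_widths[l], cl)
    params[[sprintf("comp%d_b", l)]] <- numeric(config$compression_widths[l])
    cin <- cl
  }
  ccat <- sum(config$compression_widths)
  params$cls_W <- lecun(ccat, config$n_classes, ccat)
  params$cls_b <- numeric(config$n_classes)
  cl <- widths[config$levels]
  params$dist_W <- lecun(cl, config$n_classes, cl)
  params$dist_b <- numeric(config$n_classes)
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL, palette = make_palette()),
            class = "histonet")
}

#' Number of trainable parameters
#' @param model A `histonet` model.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

# Full forward pass. Returns per-pixel class probabilities, the distribution
# head output and (optionally) the cache needed for backprop.
histonet_fwd <- function(model, x, stochastic = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  if (length(d) != 3L || d[3] != cfg$in_channels)
    stop("input must be an H x W x ", cfg$in_channels, " array")
  if (d[1] %% 2L^cfg$levels != 0L || d[2] %% 2L^cfg$levels != 0L)
    stop("input spatial dims must be divisible by 2^levels = ", 2L^cfg$levels)
  H <- d[1]; W <- d[2]
  feats <- vector("list", cfg$levels)
  caches <- list(levels = vector("list", cfg$levels))
  cur <- x
  for (l in seq_len(cfg$levels)) {
    lc <- list()
    cv <- conv_forward(cur, p[[sprintf("reduce%d_W", l)]],
                       p[[sprintf("reduce%d_b", l)]], k = 3L, stride = 2L, pad = 1L)
    lc$reduce <- cv$cache
    se <- selu_forward(cv$out); lc$reduce_selu <- se$cache
    dr <- alpha_dropout_forward(se$out, cfg$dropout_rate, stochastic)
    lc$dropout <- dr$cache
    cur <- dr$out
    lc$blocks <- vector("list", cfg$blocks_per_level)
    for (m in seq_len(cfg$blocks_per_level)) {
      pre <- sprintf("block%d_%d", l, m)
      bc <- list(x = cur)
      c1 <- conv_forward(cur, p[[paste0(pre, "_W1")]], p[[paste0(pre, "_b1")]], 1L, 1L, 0L)
      bc$c1 <- c1$cache
      s1 <- selu_forward(c1$out); bc$s1 <- s1$cache
      c2 <- conv_forward(s1$out, p[[paste0(pre, "_W2")]], p[[paste0(pre, "_b2")]], 3L, 1L, 1L)
      bc$c2 <- c2$cache
      s2 <- selu_forward(c2$out); bc$s2 <- s2$cache
      c3 <- conv_forward(s2$out, p[[paste0(pre, "_W3")]], p[[paste0(pre, "_b3")]], 1L, 1L, 0L)
      bc$c3 <- c3$cache
      pre_act <- bc$x + c3$out
      so <- selu_forward(pre_act); bc$s_out <- so$cache
      cur <- so$out
      lc$blocks[[m]] <- bc
    }
    feats[[l]] <- cur
    caches$levels[[l]] <- lc
  }
  # semantic head
  ups <- vector("list", cfg$levels)
  caches$comp <- vector("list", cfg$levels)
  caches$up <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    cp <- conv_forward(feats[[l]], p[[sprintf("comp%d_W", l)]],
                       p[[sprintf("comp%d_b", l)]], 1L, 1L, 0L)
    caches$comp[[l]] <- cp$cache
    up <- upsample_forward(cp$out, H, W)
    caches$up[[l]] <- up$cache
    ups[[l]] <- up$out
  }
  zcat <- array(0, c(H, W, sum(cfg$compression_widths)))
  off <- 0L
  for (l in seq_len(cfg$levels)) {
    cw <- cfg$compression_widths[l]
    zcat[, , off + seq_len(cw)] <- ups[[l]]
    off <- off + cw
  }
  cls <- conv_forward(zcat, p$cls_W, p$cls_b, 1L, 1L, 0L)
  caches$cls <- cls$cache
  probs <- softmax_rows(matrix(cls$out, ncol = cfg$n_classes))
  prob_map <- array(probs, c(H, W, cfg$n_classes))
  # distribution head
  deep <- feats[[cfg$levels]]
  dd <- dim(deep)
  g <- colMeans(matrix(deep, ncol = dd[3]))
  zd <- as.vector(g %*% p$dist_W + p$dist_b)
  dist <- softmax_rows(matrix(zd, 1))[1, ]
  caches$g <- g
  caches$deep_dims <- dd
  caches$probs <- probs
  caches$dist <- dist
  list(prob = prob_map, dist = dist,
       cache = if (keep_cache) caches else NULL)
}

# Backward pass from gradients wrt the per-pixel probabilities (dP, HW x 8)
# and the distribution output (ddist, length 8). Returns gradients for every
# parameter.
histonet_bwd <- function(model, cache, dP, ddist) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  # through the two softmaxes
  dZ <- softmax_backprop(dP, cache$probs)
  dzd <- softmax_backprop(matrix(ddist, 1), matrix(cache$dist, 1))[1, ]
  # classifier
  cls_dims <- cache$cls$dims
  dZarr <- array(dZ, c(cls_dims[1], cls_dims[2], cfg$n_classes))
  cb <- conv_backward(dZarr, cache$cls)
  grads$cls_W <- cb$dW; grads$cls_b <- cb$db
  dzcat <- cb$dx
  dfeat <- vector("list", cfg$levels)
  off <- 0L
  for (l in seq_len(cfg$levels)) {
    cw <- cfg$compression_widths[l]
    dup <- dzcat[, , off + seq_len(cw), drop = FALSE]
    off <- off + cw
    dcomp <- upsample_backward(dup, cache$up[[l]])
    cbk <- conv_backward(dcomp, cache$comp[[l]])
    grads[[sprintf("comp%d_W", l)]] <- cbk$dW
    grads[[sprintf("comp%d_b", l)]] <- cbk$db
    dfeat[[l]] <- cbk$dx
  }
  # distribution head into the deepest features
  grads$dist_W <- outer(cache$g, dzd)
  grads$dist_b <- dzd
  dg <- as.vector(p$dist_W %*% dzd)
  dd <- cache$deep_dims
  npix <- dd[1] * dd[2]
  dfeat[[cfg$levels]] <- dfeat[[cfg$levels]] +
    aperm(array(rep(dg / npix, each = npix), dd), c(1, 2, 3))
  # encoder, deepest level first
  dcur <- NULL
  for (l in rev(seq_len(cfg$levels))) {
    lc <- cache$levels[[l]]
    dcur <- if (is.null(dcur)) dfeat[[l]] else dcur + dfeat[[l]]
    for (m in rev(seq_len(cfg$blocks_per_level))) {
      pre <- sprintf("block%d_%d", l, m)
      bc <- lc$blocks[[m]]
      ds <- selu_backward(dcur, bc$s_out)
      b3 <- conv_backward(ds, bc$c3)
      grads[[paste0(pre, "_W3")]] <- b3$dW; grads[[paste0(pre, "_b3")]] <- b3$db
      ds2 <- selu_backward(b3$dx, bc$s2)
      b2 <- conv_backward(ds2, bc$c2)
      grads[[paste0(pre, "_W2")]] <- b2$dW; grads[[paste0(pre, "_b2")]] <- b2$db
      ds1 <- selu_backward(b2$dx, bc$s1)
      b1 <- conv_backward(ds1, bc$c1)
      grads[[paste0(pre, "_W1")]] <- b1$dW; grads[[paste0(pre, "_b1")]] <- b1$db
      dcur <- ds + b1$dx          # residual: gradient flows through both paths
    }
    dcur <- alpha_dropout_backward(dcur, lc$dropout)
    dcur <- selu_backward(dcur, lc$reduce_selu)
    rb <- conv_backward(dcur, lc$reduce)
    grads[[sprintf("reduce%d_W", l)]] <- rb$dW
    grads[[sprintf("reduce%d_b", l)]] <- rb$db
    dcur <- rb$dx
  }
  grads
}

#' Run the network on a single patch
#'
#' With `stochastic = FALSE` dropout is disabled and the output is
#' deterministic; with `stochastic = TRUE` Alpha-Dropout is active (seeded via
#' `seed`), which is the sampling mechanism behind the uncertainty maps.
#'
#' @param model A `histonet` model.
#' @param patch H x W x 3 RGB array; spatial dims divisible by `2^levels`.
#' @param stochastic Apply Alpha-Dropout during the pass.
#' @param seed Optional seed for the stochastic pass.
#' @return List with `prob` (H x W x 8 per-pixel class probabilities, each
#'   pixel on the simplex) and `dist` (length-8 tissue distribution).
#' @export
net_forward <- function(model, patch, stochastic = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- histonet_fwd(model, patch, stochastic = stochastic)
  out[c("prob", "dist")]
}

#' Normalized tissue distribution of an annotation
#'
#' The target of the auxiliary distribution head: `probs[i]` is the fraction
#' of pixels annotated with class id `i - 1`.
#'
#' @param annotation Integer label matrix with values 0..7.
#' @return Length-8 numeric vector summing to 1.
#' @export
true_distribution <- function(annotation) {
  stopifnot_labels(annotation)
  tabulate(as.vector(annotation) + 1L, nbins = 8L) / length(annotation)
}

# ---- losses -----------------------------------------------------------------

EPS_PROB <- 1e-7
EPS_DICE <- 1e-6

cce_loss <- function(probs, tidx) {
  pt <- pmin(pmax(probs[cbind(seq_along(tidx), tidx)], EPS_PROB), 1)
  n <- length(tidx)
  dP <- matrix(0, n, ncol(probs))
  dP[cbind(seq_len(n), tidx)] <- -1 / (pt * n)
  list(value = mean(-log(pt)), dP = dP)
}

ddl_loss <- function(probs, tidx) {
  present <- sort(unique(tidx))
  m <- length(present)
  dP <- matrix(0, nrow(probs), ncol(probs))
  dice <- numeric(m)
  for (j in seq_len(m)) {
    cl <- present[j]
    t <- as.numeric(tidx == cl)
    pcl <- probs[, cl]
    num <- 2 * sum(pcl * t) + EPS_DICE
    den <- sum(pcl) + sum(t) + EPS_DICE
    dice[j] <- num / den
    dP[, cl] <- -(2 * t * den - num) / (m * den^2)
  }
  list(value = 1 - mean(dice), dP = dP)
}

mse_dist_loss <- function(dist, tdist) {
  k <- length(dist)
  list(value = mean((dist - tdist)^2), ddist = 2 * (dist - tdist) / k)
}

#' Three-term training loss
#'
#' `total = cce + ddl + mse`: per-pixel categorical cross-entropy (natural
#' log, probabilities clamped to \[1e-7, 1\]), dice-distance loss (one minus
#' the soft Dice coefficient averaged over the classes present in the
#' annotation, smoothing 1e-6), and the mean squared error of the auxiliary
#' tissue-distribution head against the annotation's true distribution. All
#' terms enter unweighted.
#'
#' @param prob_map H x W x 8 per-pixel probability array.
#' @param pred_dist Length-8 predicted tissue distribution.
#' @param annotation H x W integer label matrix (0..7).
#' @return Object of class `loss_breakdown`: list with `cce`, `ddl`, `mse`,
#'   `total`.
#' @export
loss_total <- function(prob_map, pred_dist, annotation) {
  stopifnot_labels(annotation)
  d <- dim(prob_map)
  stopifnot(d[1] == nrow(annotation), d[2] == ncol(annotation))
  probs <- matrix(prob_map, ncol = d[3])
  tidx <- as.vector(annotation) + 1L
  cce <- cce_loss(probs, tidx)
  ddl <- ddl_loss(probs, tidx)
  mse <- mse_dist_loss(pred_dist, true_distribution(annotation))
  structure(list(cce = cce$value, ddl = ddl$value, mse = mse$value,
                 total = cce$value + ddl$value + mse$value),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f = cce %.4f + ddl %.4f + mse %.4f\n",
              x$total, x$cce, x$ddl, x$mse))
  invisible(x)
}

# ---- training ---------------------------------------------------------------

random_augment <- function(image, annotation, basis, magnitude) {
  if (runif(1) < 0.5) { image <- image[rev(seq_len(nrow(annotation))), , , drop = FALSE]
                        annotation <- annotation[rev(seq_len(nrow(annotation))), , drop = FALSE] }
  if (runif(1) < 0.5) { image <- image[, rev(seq_len(ncol(annotation))), , drop = FALSE]
                        annotation <- annotation[, rev(seq_len(ncol(annotation))), drop = FALSE] }
  rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  k <- if (nrow(annotation) == ncol(annotation)) sample(0:3, 1) else 0L
  if (k > 0) for (i in seq_len(k)) {
    annotation <- rot90m(annotation)
    image <- {
      tr <- aperm(image, c(2, 1, 3))
      tr[rev(seq_len(dim(tr)[1])), , , drop = FALSE]
    }
  }
  sh <- dim(annotation)
  dr <- sample(-(sh[1] %/% 4):(sh[1] %/% 4), 1)
  dc <- sample(-(sh[2] %/% 4):(sh[2] %/% 4), 1)
  roll <- function(v, n, s) v[((seq_len(n) - 1L - s) %% n) + 1L]
  annotation <- annotation[roll(seq_len(sh[1]), sh[1], dr), roll(seq_len(sh[2]), sh[2], dc), drop = FALSE]
  image <- image[roll(seq_len(sh[1]), sh[1], dr), roll(seq_len(sh[2]), sh[2], dc), , drop = FALSE]
  if (!is.null(basis) && magnitude > 0)
    image <- augment_stain(image, basis, rep(magnitude, 3), seed = sample.int(2^30, 1))
  list(image = image, annotation = annotation)
}

adam_step <- function(params, grads, state, lr, wd, t) {
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a segmentation model
#'
#' Stochastic gradient training with the Adam update rule plus L2 weight
#' decay, one patch per step, Alpha-Dropout active, and per-iteration
#' geometric (flips, 90-degree rotations, integer translations) and stain
#' augmentation. Training aborts with a diagnostic if the loss diverges to
#' NaN. A fixed `config$seed` makes the whole run reproducible.
#'
#' @param model A `histonet` model from [build_model()].
#' @param dataset List of samples, each a list with `image` (H x W x 3) and
#'   `annotation` (H x W labels); all images must share one shape.
#' @param config A [train_config()].
#' @return The trained model, with a `history` data frame (per-epoch mean
#'   `cce`, `ddl`, `mse`, `total` and training `macro_f1`).
#' @export
train_histonet <- function(model, dataset, config = train_config()) {
  stopifnot(length(dataset) >= 1L, inherits(config, "train_config"))
  shapes <- vapply(dataset, function(s) dim(s$image)[1:2], integer(2))
  if (any(shapes != shapes[, 1])) stop("all images must share one shape")
  set.seed(config$seed)
  basis <- if (config$augment) {
    px <- do.call(rbind, lapply(dataset, function(s) {
      m <- flatten_rgb(s$image)
      m[sample.int(nrow(m), min(2000L, nrow(m))), , drop = FALSE]
    }))
    stain_basis(px)
  } else NULL
  params <- model$params
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  t <- 0L
  hist_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(dataset))
    sums <- c(cce = 0, ddl = 0, mse = 0, total = 0)
    conf_pred <- integer(0); conf_true <- integer(0)
    for (i in ord) {
      s <- dataset[[i]]
      if (config$augment) {
        s <- random_augment(s$image, s$annotation, basis, config$stain_magnitude)
      }
      model$params <- params
      fw <- histonet_fwd(model, s$image, stochastic = TRUE, keep_cache = TRUE)
      tidx <- as.vector(s$annotation) + 1L
      probs <- fw$cache$probs
      cce <- cce_loss(probs, tidx)
      ddl <- ddl_loss(probs, tidx)
      mse <- mse_dist_loss(fw$dist, true_distribution(s$annotation))
      total <- cce$value + ddl$value + mse$value
      if (!is.finite(total))
        stop(sprintf("training diverged at epoch %d (loss = %s); lower the learning rate",
                     ep, format(total)))
      grads <- histonet_bwd(model, fw$cache, cce$dP + ddl$dP, mse$ddist)
      t <- t + 1L
      up <- adam_step(params, grads, state, config$learning_rate,
                      config$weight_decay, t)
      params <- up$params; state <- up$state
      sums <- sums + c(cce$value, ddl$value, mse$value, total)
      pred <- max.col(probs) - 1L
      conf_pred <- c(conf_pred, pred); conf_true <- c(conf_true, tidx - 1L)
    }
    n <- length(dataset)
    hist_rows[[ep]] <- data.frame(epoch = ep, cce = sums[1] / n, ddl = sums[2] / n,
                                  mse = sums[3] / n, total = sums[4] / n,
                                  macro_f1 = macro_f1(conf_pred, conf_true))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist_rows)
  rownames(model$history) <- NULL
  model$train_config <- config
  model$stain_basis <- basis
  model
}

#' Macro-averaged F1 score
#'
#' Per-class F1 averaged with equal weight over the classes present in the
#' reference labels (classes the reference lacks are ignored; a class the
#' prediction never hits contributes 0).
#'
#' @param pred,truth Integer label vectors/matrices of equal length.
#' @return Scalar in \[0, 1\].
#' @export
macro_f1 <- function(pred, truth) {
  pred <- as.vector(pred); truth <- as.vector(truth)
  stopifnot(length(pred) == length(truth))
  f1 <- vapply(sort(unique(truth)), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

# ---- S3 fitting interface ---------------------------------------------------

#' Fit the tissue-segmentation network
#'
#' The single entry point for model fitting: builds the network from `config`
#' and trains it on `(image, annotation)` pairs. The returned object supports
#' `print`, `summary`, `plot` (loss history) and `predict` (tiled stochastic
#' whole-image inference, see [predict.histonet()]).
#'
#' @param dataset List of training samples (`image`, `annotation`).
#' @param config A [net_config()].
#' @param train A [train_config()].
#' @return A fitted object of class `histonet`.
#' @examples
#' \donttest{
#' tiles <- lapply(1:4, function(i) synth_tissue_sample(
#'   synth_layout(c(32, 32), list(region_rect(0, 0, 0, 32, 32),
#'                                region_rect(2, 0, 16, 16, 16))), seed = i))
#' fit <- histonet(tiles, net_config(levels = 2, base_width = 8,
#'                                   compression_widths = c(4, 6)),
#'                 train_config(epochs = 2))
#' print(fit)
#' }
#' @export
histonet <- function(dataset, config = net_config(), train = train_config()) {
  model <- build_model(config)
  train_histonet(model, dataset, train)
}

#' @export
print.histonet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Tissue segmentation network (%d levels, base width %d, %s)\n",
              cfg$levels, cfg$base_width,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d classes, %d parameters, dropout %.2f\n",
              cfg$n_classes, n_parameters(x), cfg$dropout_rate))
  if (x$trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final epoch %d: total loss %.4f, training macro F1 %.3f\n",
                last$epoch, last$total, last$macro_f1))
  }
  invisible(x)
}

#' @export
summary.histonet <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nLoss history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.histonet <- function(x, ...) {
  if (!x$trained) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$cce, h$ddl, h$mse),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "steelblue", "darkgreen"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "cce", "ddl", "mse"), lty = 1, lwd = 2,
                   col = c("black", "firebrick", "steelblue", "darkgreen"))
  invisible(x)
}
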