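test_that("foreground selection keeps tissue and drops background", {
  white <- array(1, c(64, 64, 3))
  expect_false(any(foreground_mask(white)))
  # dark disc on white
  img <- array(1, c(64, 64, 3))
  rows <- matrix(0:63, 64, 64); cols <- t(rows)
  disc <- (rows - 32)^2 + (cols - 32)^2 <= 20^2
  for (ch in 1:3) img[, , ch][disc] <- 0.3
  m <- foreground_mask(img)
  expect_gte(sum(m & disc) / sum(m | disc), 0.95)
})

test_that("25%-overlap tiling enumerates the expected grid and always covers", {
  g <- tile_grid(100, 100, 40, 0.25)
  expect_equal(sort(unique(g$row0)), c(0L, 30L, 60L))
  expect_equal(sort(unique(g$col0)), c(0L, 30L, 60L))
  expect_equal(nrow(g), 9L)
  # zero overlap with an exact fit: disjoint tiling
  g0 <- tile_grid(80, 80, 40, 0)
  expect_equal(nrow(g0), 4L)
  cov <- matrix(0L, 80, 80)
  for (i in seq_len(nrow(g0)))
    cov[g0$row0[i] + seq_len(40), g0$col0[i] + seq_len(40)] <-
      cov[g0$row0[i] + seq_len(40), g0$col0[i] + seq_len(40)] + 1L
  expect_true(all(cov == 1L))
  # fuzzed coverage property
  set.seed(12)
  for (rep in 1:20) {
    h <- sample(30:90, 1); w <- sample(30:90, 1)
    ps <- sample(10:min(h, w), 1); ov <- runif(1, 0, 0.6)
    g <- tile_grid(h, w, ps, ov)
    cov <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(g)))
      cov[g$row0[i] + seq_len(g$height[i]), g$col0[i] + seq_len(g$width[i])] <- TRUE
    expect_true(all(cov))
    expect_true(all(g$row0 >= 0 & g$row0 + g$height <= h))
  }
  expect_error(tile_grid(20, 20, 30), "exceeds")
})

test_that("stochastic prediction matches recomputation from stored samples", {
  m <- build_model(tiny_config(dropout_rate = 0.2))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- predict_stochastic(m, x, n_samples = 4, seed = 3, return_samples = TRUE)
  stack <- simplify2array(out$samples)            # H x W x 8 x n
  expect_equal(out$mean, apply(stack, 1:3, mean), tolerance = 1e-6)
  expect_equal(out$var, apply(stack, 1:3, function(v) mean(v^2) - mean(v)^2),
               tolerance = 1e-6)
  # single sample or dropout-free model: zero variance
  expect_true(all(predict_stochastic(m, x, n_samples = 1, seed = 1)$var == 0))
  m0 <- build_model(tiny_config(dropout_rate = 0))
  expect_true(all(predict_stochastic(m0, x, n_samples = 5, seed = 1)$var == 0))
})

test_that("tile merging is a partition of unity and preserves constants", {
  shape <- c(60L, 50L)
  g <- tile_grid(shape[1], shape[2], 20, 0.25)
  expect_equal(tile_weight_field(g, shape), matrix(1, shape[1], shape[2]),
               tolerance = 1e-6)
  # random grids keep the property
  set.seed(3)
  for (rep in 1:10) {
    h <- sample(40:80, 1); w <- sample(40:80, 1); ps <- sample(15:30, 1)
    gg <- tile_grid(h, w, ps, runif(1, 0, 0.5))
    expect_equal(tile_weight_field(gg, c(h, w)), matrix(1, h, w), tolerance = 1e-6)
  }
  # constant tiles merge to the constant map
  const <- array(rep(c(0.7, 0.3, rep(0, 6)), each = 400), c(20, 20, 8))
  tiles <- lapply(seq_len(nrow(g)), function(i)
    list(mean = const, var = const * 0.1))
  merged <- merge_tiles(tiles, g, shape)
  expect_equal(merged$mean[, , 1], matrix(0.7, shape[1], shape[2]), tolerance = 1e-6)
  expect_equal(merged$var[, , 1], matrix(0.07, shape[1], shape[2]), tolerance = 1e-6)
  # single tile covering everything: identity
  g1 <- tile_grid(20, 20, 20, 0)
  one <- list(mean = random_prob_map(20, 20), var = array(runif(3200), c(20, 20, 8)))
  m1 <- merge_tiles(list(one), g1, c(20, 20))
  expect_equal(m1$mean, one$mean, tolerance = 1e-12)
})

test_that("argmax labeling matches a per-pixel loop and breaks ties low", {
  onehot <- array(0, c(4, 4, 8)); onehot[, , 6] <- 1
  expect_true(all(argmax_labels(onehot) == 5L))
  tie <- array(0, c(2, 2, 8)); tie[, , 1] <- 0.5; tie[, , 3] <- 0.5
  expect_true(all(argmax_labels(tie) == 0L))      # TUM wins the TUM/NEC tie
  set.seed(4)
  pm <- random_prob_map(12, 12)
  lab <- argmax_labels(pm)
  for (i in 1:12) for (j in 1:12)
    expect_identical(lab[i, j], which.max(pm[i, j, ]) - 1L)
})

test_that("variance rendering mixes class colors and normalizes globally", {
  vol <- array(0, c(8, 8, 8))
  vol[1:4, , class_id("BLC") + 1L] <- 0.3
  vol[1:4, , class_id("NEC") + 1L] <- 0.3
  rgb <- render_variance(vol)
  expect_equal(unique(as.vector(rgb[1:4, , 1] / rgb[1:4, , 2])), 0.5)  # light green
  expect_equal(unique(as.vector(rgb[1:4, , 3])), 0)
  expect_true(all(rgb[5:8, , ] == 0))
  # channel ratios invariant to scaling the variance volume
  rgb2 <- render_variance(vol * 7)
  expect_equal(rgb2, rgb, tolerance = 1e-12)
  expect_true(all(render_variance(vol * 0) == 0))
  # variance only on MST (blue): no red in the rendering
  vol_m <- array(0, c(4, 4, 8)); vol_m[, , class_id("MST") + 1L] <- 0.2
  expect_true(all(render_variance(vol_m)[, , 1] == 0))
  # label rendering paints display colors
  lab <- matrix(c(0L, 2L), 1, 2)
  img <- render_labels(lab)
  expect_equal(as.vector(img[1, 1, ]), c(1, 0, 0))
  expect_equal(as.vector(img[1, 2, ]), c(1, 1, 0))
})

test_that("whole-image prediction keeps per-pixel maps on the simplex", {
  tiles <- synth_benchmark(6, c(32, 32), seed = 77)
  fit <- histonet(tiles, tiny_config(seed = 5),
                  train_config(learning_rate = 2e-3, epochs = 3, seed = 2))
  mosaic <- synth_benchmark(1, c(48, 48), seed = 99)[[1]]
  pred <- predict(fit, mosaic$image, patch_size = 32, overlap = 0.25,
                  samples = 3, seed = 4)
  sums <- apply(pred$mean, c(1, 2), sum)
  expect_equal(sums, matrix(1, 48, 48), tolerance = 1e-6)
  expect_true(all(pred$var >= 0))
  expect_equal(dim(pred$labels), c(48L, 48L))
  expect_true(all(pred$labels %in% 0:7))
  expect_output(print(pred), "tissue prediction")
})
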