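test_that("texture features behave on degenerate and analytic patches", {
  flat <- array(0.5, c(16, 16, 3))
  fv <- texture_features(flat)
  expect_equal(unname(fv["glcm_contrast"]), 0)
  expect_equal(unname(fv[c("mom_r_sd", "mom_g_sd", "mom_b_sd")]), c(0, 0, 0),
               ignore_attr = TRUE)
  lbp <- fv[grepl("^lbp_", names(fv))]
  expect_equal(sum(lbp), 1, tolerance = 1e-12)
  expect_equal(max(lbp), 1)        # all mass on the flat (all-ones) pattern
  expect_error(texture_features(array(0.5, c(4, 4, 3))), "small")
})

test_that("GLCM contrast on a 1-px checkerboard matches a direct tally", {
  g <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)   # values 0 / 1
  cfg <- texture_config(n_levels = 256L, offsets = list(c(0L, 1L)))
  p <- glcm(g, c(0L, 1L), 256L)
  lev <- 0:255
  contrast <- sum(p * outer(lev, lev, function(a, b) (a - b)^2))
  # direct co-occurrence tally: every horizontal pair jumps 0 <-> 255
  tally <- matrix(0, 256, 256)
  q <- pmin(floor(g * 256), 255)
  for (i in 1:12) for (j in 1:11) {
    tally[q[i, j] + 1, q[i, j + 1] + 1] <- tally[q[i, j] + 1, q[i, j + 1] + 1] + 1
    tally[q[i, j + 1] + 1, q[i, j] + 1] <- tally[q[i, j + 1] + 1, q[i, j] + 1] + 1
  }
  expect_equal(p, tally / sum(tally), ignore_attr = TRUE)
  expect_equal(contrast, 255^2)
})

test_that("rotation-invariant configuration is stable under 90-degree rotation", {
  set.seed(6)
  patch <- synth_benchmark(1, c(24, 24), seed = 8)[[1]]$image
  rot <- function(img) {
    tr <- aperm(img, c(2, 1, 3))
    tr[rev(seq_len(dim(tr)[1])), , , drop = FALSE]
  }
  cfg <- texture_config(lbp_mapping = "riu2")
  f1 <- texture_features(patch, cfg)
  f2 <- texture_features(rot(patch), cfg)
  keep <- !grepl("^tamura", names(f1))   # Tamura edge handling is not exactly symmetric
  expect_equal(f1[keep], f2[keep], tolerance = 1e-8)
})

test_that("balanced patch sampling yields equal class counts", {
  tiles <- synth_benchmark(8, c(48, 48), seed = 51)
  smp <- sample_class_patches(tiles, patch_size = 8, per_class = 10, seed = 1)
  counts <- table(smp$labels)
  expect_true(all(counts == counts[1]))
  expect_lte(max(counts), 10)
  for (i in seq_along(smp$patches))
    expect_equal(dim(smp$patches[[i]]), c(8L, 8L, 3L))
})

test_that("the baseline is perfect on trivially separable constant textures", {
  cols <- palette_colors()
  tiles <- lapply(1:16, function(i) {
    ann <- matrix(rep(0:3, each = 8 * 32), 32, 32)  # four horizontal class bands
    img <- array(0, c(32, 32, 3))
    for (ch in 1:3) img[, , ch] <- matrix(cols[ann + 1L, ch], 32, 32)
    set.seed(i)
    img <- pmin(pmax(img + array(rnorm(32 * 32 * 3, 0, 0.01), dim(img)), 0), 1)
    list(image = img, annotation = ann)
  })
  bl <- suppressWarnings(
    baseline_cv(tiles, "random_forest", folds = 3, seed = 2, patch_size = 8,
                per_class = 64))
  expect_equal(bl$mean_f1, 1.0)
})

test_that("shuffled labels drop the baseline to chance", {
  tiles <- synth_benchmark(8, c(48, 48), seed = 52)
  smp <- sample_class_patches(tiles, patch_size = 8, per_class = 8, seed = 3)
  feats <- t(vapply(smp$patches, texture_features,
                    texture_features(smp$patches[[1]]), config = texture_config()))
  set.seed(4)
  y <- factor(sample(smp$labels))
  folds <- stratified_folds(y, k = 3, seed = 1)
  f1s <- vapply(1:3, function(f) {
    tr <- folds != f
    sc <- minmax_scale(feats[tr, , drop = FALSE], feats[!tr, , drop = FALSE])
    fit <- e1071::svm(minmax_scale(feats[tr, , drop = FALSE])$scaled, y[tr],
                      kernel = "radial")
    pred <- predict(fit, sc$scaled)
    macro_f1(as.integer(as.character(pred)), as.integer(as.character(y[!tr])))
  }, 0)
  expect_lt(mean(f1s), 2.5 / nlevels(y))   # near 1/n_classes, not separable
})

test_that("random forest path runs and reports the metric block", {
  tiles <- synth_benchmark(6, c(32, 32), seed = 53)
  # classes with no pure patch in this small draw are excluded with a warning
  expect_warning(
    bl <- baseline_cv(tiles, "random_forest", folds = 3, seed = 2,
                      patch_size = 8, per_class = 8),
    "excluded")
  expect_equal(nrow(bl$per_fold), 3L)
  expect_true(all(bl$per_fold$f1 >= 0 & bl$per_fold$f1 <= 1))
  map <- baseline_predict_map(bl, tiles[[1]]$image)
  expect_equal(dim(map), c(32L, 32L))
  expect_true(all(map %in% 0:7))
})
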