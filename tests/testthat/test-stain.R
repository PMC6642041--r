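test_that("color statistics match a hand-computed transform of two pixels", {
  # independent oracle: explicit matrix chain on two RGB values
  M <- matrix(c(0.3811, 0.5783, 0.0402,
                0.1967, 0.7244, 0.0782,
                0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  B <- matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
  D <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2)))
  px <- rbind(c(0.8, 0.2, 0.4), c(0.3, 0.6, 0.9))
  lab <- t(D %*% B %*% log10(M %*% t(px)))
  img <- array(0, c(1, 2, 3))
  img[1, 1, ] <- px[1, ]; img[1, 2, ] <- px[2, ]
  st <- color_stats(img)
  expect_equal(st$mean, colMeans(lab), tolerance = 1e-10)
  expect_equal(st$sd, apply(lab, 2, sd), tolerance = 1e-10)
})

test_that("constant images have zero spread; masks restrict the statistics", {
  img <- array(0.5, c(8, 8, 3))
  expect_equal(color_stats(img)$sd, c(0, 0, 0))
  # two distinct halves, mask selects the left half only
  img[, 5:8, 1] <- 0.9
  mask <- matrix(FALSE, 8, 8); mask[, 1:4] <- TRUE
  st <- color_stats(img, mask)
  left <- array(img[, 1:4, ], c(8, 4, 3))
  ref <- color_stats(left)
  expect_equal(st$mean, ref$mean)
  expect_equal(st$sd, ref$sd)
  expect_error(color_stats(img, mask & FALSE), "no pixels")
})

test_that("Reinhard normalization is the identity on its own statistics and idempotent", {
  img <- 0.2 + 0.6 * synth_benchmark(1, c(32, 32), seed = 9)[[1]]$image
  st <- color_stats(img)
  expect_lt(max(abs(reinhard_normalize(img, st, st) - img)), 1e-3)
  tgt <- color_stats(0.2 + 0.6 * synth_benchmark(1, c(32, 32), seed = 10)[[1]]$image)
  out <- reinhard_normalize(img, st, tgt)
  so <- color_stats(out)
  expect_lt(max(abs(so$mean - tgt$mean)), 1e-3)
  expect_lt(max(abs(so$sd - tgt$sd)), 1e-3)
  expect_true(all(out >= 0 & out <= 1))
  out2 <- reinhard_normalize(out, color_stats(out), tgt)
  expect_lt(max(abs(out2 - out)), 1e-3)
  # degenerate guard: constant tiles are shifted, not blown up
  flat <- array(0.4, c(4, 4, 3))
  expect_silent(reinhard_normalize(flat, color_stats(flat), tgt))
})

test_that("principal color basis recovers variance structure", {
  set.seed(1)
  # variance along a single direction
  dirv <- c(1, 1, 0) / sqrt(2)
  px <- 0.5 + outer(rnorm(500, 0, 0.1), dirv)
  b <- stain_basis(px)
  expect_gt(abs(sum(b$components[, 1] * dirv)), 0.999)
  expect_equal(b$explained_variance, sort(b$explained_variance, decreasing = TRUE))
  expect_equal(crossprod(b$components), diag(3), tolerance = 1e-6)
  # trace preservation on an arbitrary cloud
  px2 <- matrix(runif(3000), ncol = 3)
  b2 <- stain_basis(px2)
  expect_equal(sum(b2$explained_variance), sum(apply(px2, 2, var)), tolerance = 1e-8)
  # isotropic cloud: similar variance on every axis
  px3 <- matrix(rnorm(3e4, 0.5, 0.05), ncol = 3)
  ev <- stain_basis(px3)$explained_variance
  expect_lt((max(ev) - min(ev)) / max(ev), 0.1)
})

test_that("stain augmentation is seeded, bounded and axis-aligned", {
  img <- synth_benchmark(1, c(32, 32), seed = 3)[[1]]$image
  b <- stain_basis(img)
  expect_identical(augment_stain(img, b, c(0, 0, 0), seed = 1), img)
  a1 <- augment_stain(img, b, c(1, 1, 1), seed = 5)
  expect_identical(a1, augment_stain(img, b, c(1, 1, 1), seed = 5))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # shift along component 1 only: pixel deltas parallel to that component
  img_mid <- 0.3 + 0.4 * img   # keep away from the clipping range
  a2 <- augment_stain(img_mid, b, c(2, 0, 0), seed = 6)
  delta <- matrix(a2 - img_mid, ncol = 3)
  resid <- delta - delta %*% b$components[, 1] %*% t(b$components[, 1])
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("stain decomposition separates counterstain from DAB", {
  # pure single-stain patches rendered from the optical-density model
  render <- function(vec, conc) {
    od <- outer(as.vector(conc), vec)
    array(pmin(pmax((256 * exp(-od) - 1) / 255, 0), 1), c(dim(conc), 3))
  }
  v_hema <- c(0.650, 0.704, 0.286); v_hema <- v_hema / sqrt(sum(v_hema^2))
  v_dab <- c(0.268, 0.570, 0.776); v_dab <- v_dab / sqrt(sum(v_dab^2))
  set.seed(2)
  conc <- matrix(1 + rnorm(32 * 32, 0, 0.05), 32, 32)
  blue <- destain_cd45(render(v_hema, conc))
  expect_lt(mean(blue$positive), 0.05 * max(blue$counterstain, blue$positive))
  brown <- destain_cd45(render(v_dab, conc))
  expect_lt(mean(brown$counterstain), 0.05 * max(brown$counterstain, brown$positive))
  # mixed patch: thresholded positive channel recovers the planted mask
  p <- synth_cd45_patch(c(64, 64), 0.25, seed = 11)
  ds <- destain_cd45(p$image)
  thr <- EBImage::otsu(EBImage::Image(ds$positive), range = range(ds$positive))
  m <- ds$positive > thr
  expect_gte(sum(m & p$mask) / sum(m | p$mask), 0.9)
  expect_true(all(ds$positive >= 0) && all(ds$counterstain >= 0))
})
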