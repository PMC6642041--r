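test_that("model construction is deterministic and width-monotone", {
  m1 <- build_model(tiny_config())
  m2 <- build_model(tiny_config())
  expect_identical(m1$params, m2$params)
  wide <- net_config(levels = 2, base_width = 12, bottleneck_factor = 2,
                     blocks_per_level = 1, compression_widths = c(3, 4), seed = 7)
  expect_gt(n_parameters(build_model(wide)), n_parameters(m1))
})

test_that("forward pass honors shape, simplex and determinism contracts", {
  m <- build_model(tiny_config())
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  o1 <- net_forward(m, x, stochastic = FALSE)
  expect_equal(dim(o1$prob), c(32, 32, 8))
  expect_length(o1$dist, 8)
  expect_equal(apply(o1$prob, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-6)
  expect_equal(sum(o1$dist), 1, tolerance = 1e-6)
  expect_identical(o1, net_forward(m, x, stochastic = FALSE))
  # stochastic passes with different seeds differ somewhere
  s1 <- net_forward(m, x, stochastic = TRUE, seed = 1)
  s2 <- net_forward(m, x, stochastic = TRUE, seed = 2)
  expect_gt(max(abs(s1$prob - s2$prob)), 0)
  # indivisible spatial dims are rejected
  expect_error(net_forward(m, array(0.5, c(30, 32, 3))), "divisible")
  expect_error(net_forward(m, array(0.5, c(32, 32, 4))), "array")
})

test_that("true distribution counts pixels exactly", {
  ann <- matrix(c(0L, 0L, 2L, 7L), 2, 2)
  expect_equal(true_distribution(ann), c(0.5, 0, 0.25, 0, 0, 0, 0, 0.25))
  expect_equal(true_distribution(matrix(5L, 3, 3)),
               c(0, 0, 0, 0, 0, 1, 0, 0))
  set.seed(8)
  ann2 <- random_label_map(32, 32)
  naive <- numeric(8)
  for (i in 1:32) for (j in 1:32) naive[ann2[i, j] + 1L] <- naive[ann2[i, j] + 1L] + 1
  expect_equal(true_distribution(ann2), naive / 1024)
})

test_that("loss terms match analytic values and naive loop oracles", {
  set.seed(21)
  h <- 8L; w <- 8L
  ann <- random_label_map(h, w)
  # perfect one-hot prediction: every term vanishes
  onehot <- array(0, c(h, w, 8))
  for (i in seq_len(h)) for (j in seq_len(w)) onehot[i, j, ann[i, j] + 1L] <- 1
  lb <- loss_total(onehot, true_distribution(ann), ann)
  expect_equal(lb$cce, 0, tolerance = 1e-6)
  expect_equal(lb$ddl, 0, tolerance = 1e-5)
  expect_equal(lb$mse, 0, tolerance = 1e-12)
  expect_equal(lb$total, 0, tolerance = 1e-5)
  # uniform prediction: cce = ln 8
  unif <- array(1 / 8, c(h, w, 8))
  expect_equal(loss_total(unif, rep(1 / 8, 8), ann)$cce, log(8), tolerance = 1e-9)
  # random maps against an independent nested-loop implementation
  pm <- random_prob_map(h, w)
  pd <- { v <- runif(8); v / sum(v) }
  got <- loss_total(pm, pd, ann)
  cce_loop <- 0
  for (i in seq_len(h)) for (j in seq_len(w))
    cce_loop <- cce_loop - log(min(max(pm[i, j, ann[i, j] + 1L], 1e-7), 1))
  cce_loop <- cce_loop / (h * w)
  present <- sort(unique(as.vector(ann)))
  dices <- numeric(0)
  for (cl in present) {
    num <- 0; s_p <- 0; s_t <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) {
      t <- as.numeric(ann[i, j] == cl)
      num <- num + pm[i, j, cl + 1L] * t
      s_p <- s_p + pm[i, j, cl + 1L]; s_t <- s_t + t
    }
    dices <- c(dices, (2 * num + 1e-6) / (s_p + s_t + 1e-6))
  }
  td <- true_distribution(ann)
  expect_equal(got$cce, cce_loop, tolerance = 1e-6)
  expect_equal(got$ddl, 1 - mean(dices), tolerance = 1e-6)
  expect_equal(got$mse, mean((pd - td)^2), tolerance = 1e-6)
  expect_equal(got$total, got$cce + got$ddl + got$mse, tolerance = 1e-12)
})

test_that("losses are equivariant under class relabeling", {
  set.seed(31)
  ann <- random_label_map(8, 8)
  pm <- random_prob_map(8, 8)
  pd <- { v <- runif(8); v / sum(v) }
  ref <- loss_total(pm, pd, ann)
  perm <- sample(0:7)
  ann_p <- matrix(perm[ann + 1L], 8, 8)
  pm_p <- pm[, , order(perm), drop = FALSE]
  got <- loss_total(pm_p, pd[order(perm)], ann_p)
  expect_equal(got$cce, ref$cce, tolerance = 1e-12)
  expect_equal(got$ddl, ref$ddl, tolerance = 1e-12)
  expect_equal(got$mse, ref$mse, tolerance = 1e-12)
})

test_that("dice distance spans [0, 1] and hits 1 on disjoint one-hots", {
  ann <- matrix(0L, 4, 4)            # all TUM
  wrong <- array(0, c(4, 4, 8)); wrong[, , 3] <- 1   # all mass on NEC
  lb <- loss_total(wrong, rep(1 / 8, 8), ann)
  expect_equal(lb$ddl, 1, tolerance = 1e-4)
  set.seed(5)
  for (i in 1:5) {
    lb <- loss_total(random_prob_map(6, 6), rep(1 / 8, 8), random_label_map(6, 6))
    expect_gte(lb$ddl, 0); expect_lte(lb$ddl, 1)
  }
})

test_that("training with zero learning rate leaves weights unchanged", {
  tiles <- synth_benchmark(1, c(16, 16), seed = 2)
  m <- build_model(tiny_config())
  fit <- train_histonet(m, tiles, train_config(learning_rate = 0, epochs = 1, seed = 1))
  expect_identical(fit$params, m$params)
})

test_that("training loss decreases on separable synthetic textures", {
  tiles <- synth_benchmark(8, c(32, 32), seed = 41)
  fit <- histonet(tiles, tiny_config(seed = 3),
                  train_config(learning_rate = 2e-3, epochs = 5, seed = 9))
  expect_true(all(diff(fit$history$total) < 0))
  expect_true(fit$trained)
  # reproducibility of the whole run
  fit2 <- histonet(tiles, tiny_config(seed = 3),
                   train_config(learning_rate = 2e-3, epochs = 5, seed = 9))
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
  expect_output(print(fit), "trained")
})
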