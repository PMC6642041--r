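test_that("absolute, tissue and relative areas follow their definitions", {
  m <- matrix(c(0L, 0L, 2L, 7L), 2, 2)
  f <- absolute_areas(m)
  expect_equal(unname(f), c(2, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(tissue_area(f), 3)            # BGR excluded
  r <- relative_areas(f)
  expect_equal(unname(r["TUM"]), 2 / 3)
  expect_equal(unname(r["NEC"]), 1 / 3)
  expect_true(is.na(r["BGR"]))
  expect_equal(unname(relative_areas(absolute_areas(matrix(0L, 4, 4)))["TUM"]), 1)
  # all background: area 0, flagged undefined
  f0 <- absolute_areas(matrix(7L, 3, 3))
  expect_equal(tissue_area(f0), 0)
  r0 <- relative_areas(f0)
  expect_false(attr(r0, "defined"))
  expect_true(all(is.na(r0)))
})

test_that("conservation and scaling hold over fuzzed maps", {
  set.seed(9)
  for (rep in 1:100) {
    m <- random_label_map(16, 16)
    f <- absolute_areas(m)
    expect_equal(sum(f), 256)
    expect_equal(tissue_area(f), 256 - f["TAR"] - f["BGR"], ignore_attr = TRUE)
    r <- relative_areas(f)
    if (attr(r, "defined")) expect_equal(sum(r[1:6]), 1, tolerance = 1e-12)
    # naive loop histogram oracle
    if (rep <= 5) {
      naive <- integer(8)
      for (i in 1:16) for (j in 1:16) naive[m[i, j] + 1L] <- naive[m[i, j] + 1L] + 1L
      expect_equal(unname(f), naive)
    }
  }
  # 2x replication upsampling: f_abs and A scale by 4, f_rel unchanged
  m <- random_label_map(8, 8)
  up <- m[rep(1:8, each = 2), rep(1:8, each = 2)]
  expect_equal(absolute_areas(up), 4L * absolute_areas(m))
  expect_equal(tissue_area(absolute_areas(up)), 4 * tissue_area(absolute_areas(m)))
  expect_equal(relative_areas(absolute_areas(up)), relative_areas(absolute_areas(m)))
})

test_that("isotype deltas vanish on self and are antisymmetric", {
  set.seed(11)
  a <- meta_features(random_label_map(12, 12), cd45_fraction = 0.3)
  b <- meta_features(random_label_map(12, 12), cd45_fraction = 0.18)
  for (which in c("TUM", "NEC", "A", "cd45")) {
    expect_equal(isotype_delta(a, a, which), 0)
    expect_equal(isotype_delta(a, b, which), -isotype_delta(b, a, which))
  }
  expect_equal(isotype_delta(a, b, "A"), a$area - b$area)
  # mode selects absolute vs relative features
  expect_equal(isotype_delta(a, b, "TUM", "abs"),
               unname(a$f_abs["TUM"] - b$f_abs["TUM"]))
  expect_equal(isotype_delta(a, b, "TUM", "rel"),
               unname(a$f_rel["TUM"] - b$f_rel["TUM"]))
  # undefined operands propagate
  z <- meta_features(matrix(7L, 4, 4))
  expect_true(is.na(isotype_delta(z, b, "TUM", "rel")))
  expect_error(isotype_delta(a, b, "XYZ"), "unknown feature")
})

test_that("CD45 fraction is positive count over counterstain count", {
  pos <- matrix(0, 20, 20); pos[1:5, 1:10] <- 1           # 50 positive px
  cs <- matrix(0, 20, 20); cs[1:10, ] <- 1                # 200 counterstain px
  expect_equal(cd45_fraction(pos, cs, 0.5, 0.5), 0.25)
  expect_equal(cd45_fraction(pos * 0, cs, 0.5, 0.5), 0)
  expect_true(is.na(cd45_fraction(pos, cs * 0, 0.5, 0.5)))
  # end-to-end: planted fraction recovered through destaining + Otsu
  p <- synth_cd45_patch(c(64, 64), 0.25, seed = 6)
  ds <- destain_cd45(p$image)
  expect_lt(abs(cd45_fraction(ds$positive, ds$counterstain) - 0.25), 0.05)
})

test_that("the cohort feature table composes the per-sample operations", {
  coh <- synth_smt_cohort(17, effect = 1, seed = 15)
  ft <- build_feature_table(coh)
  expect_equal(nrow(ft$features), 51L)       # 17 models x 3 treated arms
  expect_named(ft$features, c("abs_TUM", "rel_TUM", "rel_MST",
                              "d_rel_NEC", "d_cd45", "d_A"))
  # compositional oracle on one row
  meta <- cohort_metadata(coh)
  i <- which(meta$treatment != "isotype")[1]
  iso <- which(meta$model_id == meta$model_id[i] & meta$treatment == "isotype")
  fs <- meta_features(coh$samples[[i]]$labels, coh$samples[[i]]$cd45_fraction)
  fi <- meta_features(coh$samples[[iso]]$labels, coh$samples[[iso]]$cd45_fraction)
  expect_equal(ft$features$abs_TUM[1], unname(fs$f_abs["TUM"]))
  expect_equal(ft$features$rel_TUM[1], unname(fs$f_rel["TUM"]))
  expect_equal(ft$features$d_rel_NEC[1], isotype_delta(fs, fi, "NEC", "rel"))
  expect_equal(ft$features$d_A[1], isotype_delta(fs, fi, "A"))
  # treated sample identical to its isotype: all deltas zero
  coh2 <- synth_smt_cohort(2, effect = 1, seed = 1)
  for (k in seq_along(coh2$samples)) {
    iso_k <- which(cohort_metadata(coh2)$model_id == coh2$samples[[k]]$model_id &
                     cohort_metadata(coh2)$treatment == "isotype")
    coh2$samples[[k]]$labels <- coh2$samples[[iso_k]]$labels
    coh2$samples[[k]]$cd45_fraction <- coh2$samples[[iso_k]]$cd45_fraction
  }
  ft2 <- build_feature_table(coh2)
  expect_true(all(abs(ft2$features$d_rel_NEC) < 1e-12))
  expect_true(all(abs(ft2$features$d_cd45) < 1e-12))
  expect_true(all(abs(ft2$features$d_A) < 1e-12))
  # a model without isotype is reported by id
  coh3 <- synth_smt_cohort(2, effect = 1, seed = 2)
  coh3$samples <- Filter(function(s)
    !(s$model_id == "PDX001" && s$treatment == "isotype"), coh3$samples)
  expect_error(build_feature_table(coh3), "PDX001")
})
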