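test_that("roi_quantile follows the (n-1)q interpolation convention", {
  expect_equal(roi_quantile(c(1, 2, 3, 4), 0.25), 1.75)
  expect_equal(roi_quantile(c(4, 1, 3, 2), 0), 1)
  expect_equal(roi_quantile(c(4, 1, 3, 2), 1), 4)
  expect_equal(roi_quantile(5, 0.3), 5)
  expect_error(roi_quantile(numeric(0), 0.5), "empty")
  # spot-check against the established type-7 implementation
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(1:50, 1), 0, 16383)
    q <- runif(1)
    expect_equal(roi_quantile(v, q),
                 unname(stats::quantile(v, q, type = 7)))
  }
})

test_that("the {1,2,3,4} worked example reproduces the derived vector", {
  px <- matrix(c(1, 2, 3, 4), 2, 2)
  fv <- extract_features(px, roi_mask(matrix(1, 2, 2)), "set2")
  expect_equal(fv, c(mean_intensity = 2.5, median_intensity = 2.5,
                     mean_iqr = 2.5, median_iqr = 2.5,
                     mean_above = 3.5, median_above = 3.5,
                     mean_below = 1.5, median_below = 1.5,
                     diff_max_median = 1.5, diff_median_min = 1.5,
                     iqr = 1.5))
  expect_equal(extract_features(px, roi_mask(matrix(1, 2, 2)), "set1"),
               c(mean_intensity = 2.5))
})

test_that("degenerate and masked inputs behave by contract", {
  uni <- extract_features(matrix(7, 3, 3), roi_mask(matrix(1, 3, 3)))
  expect_true(all(uni[1:8] == 7))
  expect_true(all(uni[9:11] == 0))

  px <- matrix(runif(36, 0, 1000), 6, 6)
  m <- matrix(0, 6, 6); m[2:4, 2:4] <- 1
  fv1 <- extract_features(px, roi_mask(m))
  px2 <- px; px2[m == 0] <- 0   # clobber everything outside the ROI
  expect_identical(fv1, extract_features(px2, roi_mask(m)))

  expect_error(extract_features(px, roi_mask(matrix(0, 6, 6))), "empty ROI")
  expect_error(extract_features(px, roi_mask(matrix(1, 3, 3))), "shapes")
})

test_that("all 11 statistics match the loop oracle on random multisets", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    v <- sample(round(runif(n, 0, 16383), sample(0:2, 1)), n, replace = TRUE)
    fv <- extract_features(matrix(v, 1), roi_mask(matrix(1, 1, n)))
    expect_equal(fv, oracle_features(v), tolerance = 1e-9)
  }
})

test_that("features are location/scale equivariant and permutation invariant", {
  set.seed(8)
  loc <- 1:8; diff_ <- 9:11
  for (i in 1:25) {
    v <- runif(sample(2:200, 1), 0, 2000)
    a <- runif(1, 0.5, 3); b <- runif(1, 0, 500)
    f0 <- extract_features(matrix(v, 1), roi_mask(matrix(1, 1, length(v))))
    f1 <- extract_features(matrix(a * v + b, 1),
                           roi_mask(matrix(1, 1, length(v))))
    expect_equal(f1[loc], a * f0[loc] + b, tolerance = 1e-12)
    expect_equal(f1[diff_], a * f0[diff_], tolerance = 1e-12)
    vp <- sample(v)
    fp <- extract_features(matrix(vp, 1), roi_mask(matrix(1, 1, length(vp))))
    expect_equal(fp, f0)
  }
})

test_that("featurize_dataset copies labels through and drops empty masks", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 4)
  manifest <- generate_dataset(cfg, dir)
  tab <- featurize_dataset(manifest)
  expect_equal(nrow(tab), nrow(manifest))
  expect_identical(tab$label, manifest$label)
  expect_identical(attr(tab, "input_set"), "set2")

  keys <- paste(manifest$ear_id, manifest$frame_index, sep = "_")
  masks <- lapply(seq_len(nrow(manifest)), function(i)
    read_mask(manifest$mask_path[i]))
  names(masks) <- keys
  masks[[1]] <- roi_mask(matrix(0L, cfg$frame_shape[1], cfg$frame_shape[2]))
  expect_warning(tab2 <- featurize_dataset(manifest, masks = masks),
                 "empty ROI")
  expect_equal(nrow(tab2), nrow(manifest) - 1)

  tab3 <- featurize_dataset(manifest)
  expect_identical(tab, tab3)
})

test_that("effusion frames score lower mean intensity in a cohort table", {
  tab <- cohort_features(tiny_config(n_ears = 12, seed = 6))
  expect_lt(mean(tab$mean_intensity[tab$label == "effusion"]),
            mean(tab$mean_intensity[tab$label == "no_effusion"]))
})
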