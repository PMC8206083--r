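test_that("static threshold and kmeans behave on toy images", {
  px <- matrix(c(10, 220, 200, 15), 2, 2, byrow = TRUE)
  m <- segment_classical(px, "static_threshold", list(thr = 100))
  expect_identical(unclass(m)[, ], matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))

  # two-level image: brightest of two clusters is exactly the bright block
  px2 <- matrix(1000, 8, 8); px2[3:6, 3:6] <- 9000
  k <- segment_classical(px2, "kmeans", list(k = 2))
  expect_identical(unclass(k)[, ] == 1L, px2 == 9000)

  expect_error(segment_classical(px, "kmeans", list(k = 1)), "k must be")
  expect_error(segment_classical(px, "magic"), "arg")
  expect_error(segment_classical(px, "adaptive_threshold", list(window = 4)),
               "odd")
})

test_that("blur detection concentrates exclusions in the smoothed half", {
  set.seed(2)
  sw <- asNamespace("swirotome")
  px <- matrix(8000 + rnorm(128 * 128, 0, 400), 128, 128)
  blurred <- sw$box_blur(px, 31L)
  px[, 65:128] <- blurred[, 65:128]
  m <- unclass(segment_classical(px, "blur_detect"))
  excluded <- m == 0L
  expect_gte(sum(excluded[, 65:128]) / sum(excluded), 0.90)
})

test_that("classical masks are deterministic", {
  cfg <- tiny_config(seed = 17)
  fm <- render_frame(sample_cohort(cfg)[[1]], 0, cfg)
  for (method in c("static_threshold", "adaptive_threshold", "kmeans",
                   "hough_circle", "active_contour", "blur_detect")) {
    m1 <- segment_classical(fm$frame, method)
    m2 <- segment_classical(fm$frame, method)
    expect_identical(unclass(m1)[, ], unclass(m2)[, ], info = method)
  }
})

test_that("evaluate_masks matches definitions and the confusion oracle", {
  mixed <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3)
  em <- evaluate_masks(roi_mask(mixed), roi_mask(mixed))
  expect_equal(unname(em), rep(1, 4))

  truth <- matrix(0, 4, 5); truth[1, 1:5] <- 1
  em2 <- evaluate_masks(roi_mask(matrix(0, 4, 5)), roi_mask(truth))
  expect_equal(em2, c(pixel_accuracy = 0.75, dice = 0,
                      roi_sensitivity = 0, roi_specificity = 1))

  set.seed(11)
  for (i in 1:100) {
    p <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    t_ <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    expect_equal(evaluate_masks(roi_mask(p), roi_mask(t_)),
                 oracle_mask_metrics(as.vector(p), as.vector(t_)))
    # accuracy is symmetric in its arguments
    expect_equal(evaluate_masks(roi_mask(p), roi_mask(t_))["pixel_accuracy"],
                 evaluate_masks(roi_mask(t_), roi_mask(p))["pixel_accuracy"])
  }
  expect_error(evaluate_masks(roi_mask(matrix(0, 2, 2)),
                              roi_mask(matrix(0, 3, 3))), "shapes")
})

test_that("empty-mask conventions hold", {
  e <- roi_mask(matrix(0, 3, 3)); f <- roi_mask(matrix(1, 3, 3))
  both <- evaluate_masks(e, e)
  expect_equal(unname(both[c("dice", "roi_sensitivity")]), c(1, 1))
  pred_full <- evaluate_masks(f, e)
  expect_equal(unname(pred_full[c("dice", "roi_sensitivity")]), c(0, 0))
})
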