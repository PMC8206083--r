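test_that("frame round-trips are bit-exact", {
  dir <- withr::local_tempdir()
  px <- matrix(c(0, 1, 16383, 2), 2, 2)
  f <- swir_frame(px, "P1", "E1", 0, "effusion")
  p <- file.path(dir, "f.pgm")
  write_frame(f, p)
  g <- read_frame(p, "P1", "E1", 0, "effusion")
  expect_identical(g$pixels, px)

  zero <- swir_frame(matrix(0, 3, 5))
  write_frame(zero, p)
  expect_equal(sum(read_frame(p)$pixels), 0)

  cfg <- tiny_config(seed = 7)
  fm <- render_frame(sample_cohort(cfg)[[1]], 0, cfg)
  write_frame(fm$frame, p)
  expect_identical(read_frame(p)$pixels, fm$frame$pixels)

  mp <- file.path(dir, "m.pgm")
  write_mask(fm$mask, mp)
  expect_identical(unclass(read_mask(mp))[, ], unclass(fm$mask)[, ])
})

test_that("frame reading rejects bad inputs", {
  dir <- withr::local_tempdir()
  expect_error(read_frame(file.path(dir, "absent.pgm")), "not found")
  ppm <- file.path(dir, "color.ppm")
  writeLines(c("P6", "1 1", "255"), ppm)
  con <- file(ppm, "ab"); writeBin(as.raw(c(1, 2, 3)), con); close(con)
  expect_error(read_frame(ppm), "multi-channel")
  txt <- file.path(dir, "junk.txt")
  writeLines("hello", txt)
  expect_error(read_frame(txt), "unreadable format")
  expect_error(swir_frame(matrix(-1, 2, 2)), "\\[0")
  expect_error(swir_frame(matrix(20000, 2, 2)), "\\[0")
})

test_that("rasterization matches the worked rectangle cases", {
  full <- rect_poly(-0.5, -0.5, 3.5, 3.5)
  ann <- swir_annotation(list(full), "include")
  expect_identical(unclass(rasterize_annotation(ann, c(4, 4)))[, ],
                   matrix(1L, 4, 4))

  ann2 <- swir_annotation(list(full, rect_poly(-0.5, -0.5, 1.5, 3.5)),
                          c("include", "exclude"))
  m2 <- rasterize_annotation(ann2, c(4, 4))
  expect_equal(sum(m2), 8)
  expect_true(all(unclass(m2)[3:4, ] == 1L))

  ann3 <- swir_annotation(list(rect_poly(0.5, 0.5, 2.5, 2.5)), "exclude")
  expect_equal(sum(rasterize_annotation(ann3, c(4, 4))), 0)

  expect_error(swir_annotation(list(rbind(c(0, 0), c(1, 1))), "include"),
               "3 vertices")
})

test_that("rasterization agrees with the brute-force oracle on random polygons", {
  set.seed(42)
  for (trial in 1:100) {
    k <- sample(1:3, 1)
    polys <- lapply(seq_len(k), function(i) {
      nv <- sample(3:8, 1)
      cbind(runif(nv, -2, 17), runif(nv, -2, 17))
    })
    polarity <- sample(c("include", "exclude"), k, replace = TRUE,
                       prob = c(0.7, 0.3))
    ann <- swir_annotation(polys, polarity)
    got <- unclass(rasterize_annotation(ann, c(16, 16)))[, ]
    expect_identical(got, oracle_rasterize(ann, c(16, 16)),
                     info = paste("trial", trial))
  }
})

test_that("annotation JSON round-trips", {
  dir <- withr::local_tempdir()
  ann <- swir_annotation(list(rect_poly(0, 0, 5.5, 7.25),
                              cbind(c(1, 2, 3), c(3, 1.5, 4))),
                         c("include", "exclude"), frame = "E01_f000")
  p <- file.path(dir, "ann.json")
  write_annotation(ann, p)
  back <- read_annotation(p)
  expect_equal(back$polygons, ann$polygons)
  expect_identical(back$polarity, ann$polarity)
  expect_identical(back$frame, "E01_f000")
})

test_that("manifest round-trips, validates labels and duplicates", {
  dir <- withr::local_tempdir()
  m <- data.frame(frame_path = c("a.pgm", "b.pgm", "c.pgm"),
                  mask_path = c("am.pgm", "bm.pgm", "cm.pgm"),
                  patient_id = "P1", ear_id = c("E1", "E1", "E2"),
                  frame_index = c(0L, 1L, 0L),
                  label = c("effusion", "effusion", "no_effusion"),
                  subset_tag = "other", stringsAsFactors = FALSE)
  p <- file.path(dir, "manifest.csv")
  write_manifest(m, p)
  expect_identical(read_manifest(p, resolve = FALSE), m)

  bad <- m; bad$label[1] <- "fluid"
  expect_error(write_manifest(bad, p), "allowed labels")
  dup <- m; dup$frame_index[2] <- 0L
  expect_error(write_manifest(dup, p), "duplicate")
  short <- m[1:2, ]; short$subset_tag <- "frame_range"
  expect_warning(write_manifest(short, p), "20-22")
})

test_that("generate_dataset writes a readable, consistent dataset", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 1)
  # tiny cohorts legitimately warn about the frame-level class fraction
  manifest <- suppressWarnings(generate_dataset(cfg, dir))
  expect_identical(read_manifest(file.path(dir, "manifest.csv")), manifest)
  expect_true(all(file.exists(manifest$frame_path)))
  expect_true(all(file.exists(manifest$mask_path)))
  f <- read_frame(manifest$frame_path[1])
  m <- read_mask(manifest$mask_path[1])
  expect_identical(dim(f$pixels), dim(unclass(m)))

  cfg1 <- synthetic_config(n_ears = 4, frames_per_ear = c(1, 1),
                           frame_shape = c(64, 80), seed = 2)
  m1 <- suppressWarnings(generate_dataset(cfg1, file.path(dir, "one")))
  expect_equal(nrow(m1), 4)
})
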