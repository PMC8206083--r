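test_that("cohort bookkeeping follows prevalence and seed", {
  cfg <- synthetic_config(seed = 11)
  ears <- sample_cohort(cfg)
  labs <- vapply(ears, `[[`, "", "label")
  expect_length(ears, 55)
  expect_equal(sum(labs == "effusion"), 19)
  expect_equal(sum(labs == "no_effusion"), 36)

  ears2 <- sample_cohort(cfg)
  expect_identical(vapply(ears, `[[`, 0, "baseline"),
                   vapply(ears2, `[[`, 0, "baseline"))

  expect_error(sample_cohort(synthetic_config(n_ears = 10, prevalence = 0.01)),
               "empty class")
})

test_that("degenerate variance gives an exact baseline shift", {
  cfg <- tiny_config(ear_sd = 0, effusion_shift = 2500, seed = 3)
  ears <- sample_cohort(cfg)
  labs <- vapply(ears, `[[`, "", "label")
  base <- vapply(ears, `[[`, 0, "baseline")
  expect_true(all(base[labs == "effusion"] == cfg$base_level - 2500))
  expect_true(all(base[labs == "no_effusion"] == cfg$base_level))
})

test_that("effusion lowers ROI intensity for label-matched ears", {
  cfg <- tiny_config(seed = 5)
  ears <- sample_cohort(cfg)
  eff <- ears[[1]]
  twin <- eff; twin$label <- "no_effusion"
  twin$baseline <- eff$baseline + cfg$effusion_shift  # same ear, fluid removed
  a <- render_frame(eff, 0, cfg)
  b <- render_frame(twin, 0, cfg)
  expect_lt(mean(a$frame$pixels[unclass(a$mask) == 1]),
            mean(b$frame$pixels[unclass(b$mask) == 1]))
})

test_that("artifact-free noiseless ears render a constant disc", {
  cfg <- synthetic_config(n_ears = 4, frame_shape = c(64, 80),
                          texture_sd = 0, cerumen_rate = 0, hair_rate = 0,
                          defocus_prob = 0, flicker_sd = 0, ear_sd = 0,
                          seed = 9)
  ears <- sample_cohort(cfg)
  ear <- ears[[3]]                      # a no-effusion ear
  ear$vignette <- 0
  fm <- render_frame(ear, 0, cfg)
  roi_vals <- fm$frame$pixels[unclass(fm$mask) == 1]
  # read noise is the only remaining dispersion
  expect_lt(sd(roi_vals), 70)
  expect_lt(abs(mean(roi_vals) - ear$baseline), 10)
})

test_that("ground-truth ROI avoids every artifact footprint", {
  cfg <- synthetic_config(seed = 3)
  ears <- sample_cohort(cfg)
  ear <- NULL
  for (e in ears) if (length(e$cerumen) && length(e$hair)) { ear <- e; break }
  expect_false(is.null(ear))
  fm <- render_frame(ear, 2, cfg)
  mask <- unclass(fm$mask) == 1
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  # independent footprint recomputation
  in_disc <- ((r - ear$center[1]) / ear$axes[1])^2 +
    ((cc - ear$center[2]) / ear$axes[2])^2 <= 1
  expect_true(all(in_disc[mask]))
  for (b in ear$cerumen) {
    foot <- ((r - b$center[1]) / b$radii[1])^2 +
      ((cc - b$center[2]) / b$radii[2])^2 <= 1
    expect_equal(sum(mask & foot), 0)
  }
  for (h in ear$hair) {
    d <- abs(-sin(h$angle) * (r - h$point[1]) + cos(h$angle) * (cc - h$point[2]))
    expect_equal(sum(mask & (d <= h$halfwidth)), 0)
  }
  if (!is.null(ear$defocus))
    expect_equal(sum(mask[(ear$defocus[1] + 1):ear$defocus[2], ]), 0)
  expect_equal(sum(mask[1:6, ]), 0)  # unlit border
  expect_gte(mean(mask), 0.10)
})

test_that("direction of effect holds across the cohort", {
  cfg <- synthetic_config(frame_shape = c(64, 80), frames_per_ear = c(2, 2),
                          seed = 21)
  ears <- sample_cohort(cfg)
  roi_mean <- vapply(ears, function(e) {
    fm <- render_frame(e, 0, cfg)
    mean(fm$frame$pixels[unclass(fm$mask) == 1])
  }, 0)
  labs <- vapply(ears, `[[`, "", "label")
  tt <- t.test(roi_mean[labs == "effusion"], roi_mean[labs == "no_effusion"],
               alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("rendering is deterministic and order-independent", {
  cfg <- tiny_config(seed = 13)
  ears <- sample_cohort(cfg)
  a1 <- render_frame(ears[[2]], 1, cfg)
  b <- render_frame(ears[[2]], 0, cfg)   # render another frame in between
  a2 <- render_frame(ears[[2]], 1, cfg)
  expect_identical(a1$frame$pixels, a2$frame$pixels)
  expect_identical(unclass(a1$mask)[, ], unclass(a2$mask)[, ])
  expect_false(identical(a1$frame$pixels, b$frame$pixels))
})
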