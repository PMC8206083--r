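# Synthetic SWIR otoscopy cohorts.
#
# The generator emulates the statistical structure the downstream analysis
# assumes, not the optics: an elliptical tympanic-membrane disc brighter than
# the unlit surround, per-ear baseline intensity lowered when an effusion is
# present (shortwave-infrared light is absorbed by middle-ear fluid), smooth
# low-frequency texture whose dispersion increases with effusion, artifacts
# (cerumen blobs, hair strokes, defocus bands, dark borders) excluded from
# the ground-truth ROI, and multiplicative AR(1) illumination flicker along
# each 20-22 frame clip.

#' Synthetic cohort configuration
#'
#' Defaults describe a cohort at the scale of a single-center tympanostomy
#' series: 55 ears with 35% effusion prevalence, clips of 20-22 consecutive
#' frames at the 320x256 14-bit sensor geometry.
#'
#' @param n_ears number of ears (default 55).
#' @param prevalence fraction of ears with an effusion (default 0.35).
#' @param frames_per_ear integer range `c(min, max)` of clip length
#'   (default 20-22 consecutive frames).
#' @param frame_shape `(rows, cols)` of each frame (default `c(256, 320)`,
#'   the 320 x 256-pixel InGaAs sensor).
#' @param base_level mean ROI intensity, in counts, of non-effusion ears
#'   (default 9000 of the 16383-count scale).
#' @param effusion_shift mean decrease in ROI intensity for effusion ears,
#'   in counts (default 2500).
#' @param ear_sd between-ear baseline standard deviation in counts
#'   (default 1200); makes the per-class intensity distributions overlap.
#' @param texture_sd standard deviation of the smooth membrane texture in
#'   counts (default 600).
#' @param heterogeneity_boost multiplier on `texture_sd` for effusion ears
#'   (default 1.5), so the full statistic set carries information beyond the
#'   mean.
#' @param cerumen_rate,hair_rate expected number of cerumen blobs / hair
#'   strokes per ear (Poisson; defaults 1.5 and 1.0).
#' @param defocus_prob probability that an ear's clip has an out-of-focus
#'   band (default 0.3).
#' @param flicker_rho,flicker_sd AR(1) autocorrelation and stationary sd of
#'   the multiplicative frame-to-frame gain (defaults 0.8 and 0.03).
#' @param seed integer seed; the cohort is fully determined by it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_ears = 55L, prevalence = 0.35,
                             frames_per_ear = c(20L, 22L),
                             frame_shape = c(256L, 320L),
                             base_level = 9000, effusion_shift = 2500,
                             ear_sd = 1200, texture_sd = 600,
                             heterogeneity_boost = 1.5,
                             cerumen_rate = 1.5, hair_rate = 1.0,
                             defocus_prob = 0.3,
                             flicker_rho = 0.8, flicker_sd = 0.03,
                             seed = 1L) {
  cfg <- list(n_ears = as.integer(n_ears), prevalence = prevalence,
              frames_per_ear = as.integer(range(frames_per_ear)),
              frame_shape = as.integer(frame_shape),
              base_level = base_level, effusion_shift = effusion_shift,
              ear_sd = ear_sd, texture_sd = texture_sd,
              heterogeneity_boost = heterogeneity_boost,
              cerumen_rate = cerumen_rate, hair_rate = hair_rate,
              defocus_prob = defocus_prob,
              flicker_rho = flicker_rho, flicker_sd = flicker_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_ears >= 2L, cfg$prevalence > 0, cfg$prevalence < 1,
            cfg$effusion_shift >= 0,
            cfg$base_level - cfg$effusion_shift >= 0,
            cfg$ear_sd >= 0, cfg$texture_sd >= 0,
            cfg$heterogeneity_boost > 0,
            cfg$cerumen_rate >= 0, cfg$hair_rate >= 0,
            cfg$defocus_prob >= 0, cfg$defocus_prob <= 1,
            cfg$flicker_sd >= 0, abs(cfg$flicker_rho) < 1,
            all(cfg$frame_shape > 0))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @param path YAML file of configuration overrides.
#' @export
read_synthetic_config <- function(path) {
  do.call(synthetic_config, yaml::read_yaml(path))
}

# Evaluate expr under a temporary RNG state; global stream untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Sub-seed derivation: one stream per (cohort seed, ear, purpose), stable
# under ear reordering. Kept below 2^31 - 1.
derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 104729 +
                as.double(salt) * 7919) %% 2147483629)
}

#' Sample the per-ear states of a synthetic cohort
#'
#' The number of effusion ears is `round(n_ears * prevalence)`; each ear's
#' baseline intensity is `base_level` (minus `effusion_shift` for effusion
#' ears) plus a Normal(0, `ear_sd`) random effect, clipped to the 14-bit
#' range. Every ear carries its own RNG stream derived from `(seed, ear)`.
#'
#' @param config a [synthetic_config()].
#' @return List of ear states (label, baseline, membrane geometry, artifact
#'   layout, clip length).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_eff <- as.integer(round(config$n_ears * config$prevalence))
  if (n_eff < 1L || n_eff >= config$n_ears)
    stop("prevalence ", config$prevalence, " yields an empty class for ",
         config$n_ears, " ears")
  labels <- c(rep("effusion", n_eff), rep("no_effusion", config$n_ears - n_eff))
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  ears <- lapply(seq_len(config$n_ears), function(i) {
    es <- derive_seed(config$seed, i)
    with_seed(es, {
      eff <- labels[i] == "effusion"
      baseline <- config$base_level - if (eff) config$effusion_shift else 0
      baseline <- min(max(baseline + rnorm(1, 0, config$ear_sd), 0), MAX_COUNT)
      center <- c(nr / 2 + runif(1, -12, 12), nc / 2 + runif(1, -12, 12))
      axes <- c(runif(1, 0.30, 0.38) * nr, runif(1, 0.30, 0.38) * nc)
      # artifact layout; resampled (bounded) if it eats the ROI below 10%
      # of the frame — the layout alone determines the ground-truth ROI
      for (attempt in 1:10) {
        n_cer <- stats::rpois(1, config$cerumen_rate)
        cerumen <- lapply(seq_len(n_cer), function(j) list(
          center = center + runif(2, -0.6, 0.6) * axes,
          radii = runif(2, 0.03, 0.085) * min(nr, nc),
          level = runif(1, 800, 2000)))
        n_hair <- stats::rpois(1, config$hair_rate)
        hair <- lapply(seq_len(n_hair), function(j) list(
          point = center + runif(2, -0.5, 0.5) * axes,
          angle = runif(1, 0, pi),
          halfwidth = runif(1, 1, 2.5),
          level = runif(1, 500, 1500)))
        defocus <- if (runif(1) < config$defocus_prob) {
          h <- round(runif(1, 0.12, 0.22) * nr)
          r0 <- round(runif(1, max(1, center[1] - axes[1]),
                            min(nr - h, center[1] + axes[1] - h)))
          c(r0, r0 + h)
        }
        frac <- roi_fraction(nr, nc, center, axes, cerumen, hair, defocus)
        if (frac >= 0.10) break
        if (attempt == 10)
          stop("artifact layout leaves ROI below 10% of the frame for ear ",
               sprintf("E%02d", i))
      }
      list(ear_id = sprintf("E%02d", i),
           patient_id = sprintf("P%02d", ceiling(i / 2)),
           label = labels[i], baseline = baseline,
           center = center, axes = axes,
           vignette = 0.15,
           texture_sd = config$texture_sd *
             if (eff) config$heterogeneity_boost else 1,
           cerumen = cerumen, hair = hair, defocus = defocus,
           n_frames = sample(seq(config$frames_per_ear[1],
                                 config$frames_per_ear[2]), 1),
           frame_start = sample(0:49, 1),
           seed = es)
    })
  })
  ears
}

# Bilinear resize, used for texture fields and segmenter input scaling.
resize_bilinear <- function(mat, nr, nc) {
  sr <- nrow(mat); sc <- ncol(mat)
  if (sr == nr && sc == nc) return(mat)
  r <- if (sr == 1L) rep(1, nr) else seq(1, sr, length.out = nr)
  cc <- if (sc == 1L) rep(1, nc) else seq(1, sc, length.out = nc)
  r0 <- if (sr == 1L) rep(1, nr) else pmin(sr - 1, floor(r))
  c0 <- if (sc == 1L) rep(1, nc) else pmin(sc - 1, floor(cc))
  fr <- r - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, sr); c1 <- pmin(c0 + 1, sc)
  top <- mat[r0, c0, drop = FALSE] * (1 - fr) + mat[r1, c0, drop = FALSE] * fr
  bot <- mat[r0, c1, drop = FALSE] * (1 - fr) + mat[r1, c1, drop = FALSE] * fr
  sweep(top, 2, 1 - fc, "*") + sweep(bot, 2, fc, "*")
}

resize_nearest <- function(mat, nr, nc) {
  ri <- pmax(1L, pmin(nrow(mat), round(seq(1, nrow(mat), length.out = nr))))
  ci <- pmax(1L, pmin(ncol(mat), round(seq(1, ncol(mat), length.out = nc))))
  mat[ri, ci, drop = FALSE]
}

# Separable box blur, edge-replicated; enough to emulate defocus.
box_blur <- function(mat, k) {
  half <- k %/% 2
  w <- rep(1 / k, k)
  m <- rbind(mat[rep(1, half), , drop = FALSE], mat,
             mat[rep(nrow(mat), half), , drop = FALSE])
  m <- apply(m, 2, function(col) stats::filter(col, w, sides = 2))
  m <- m[(half + 1):(half + nrow(mat)), , drop = FALSE]
  m <- cbind(m[, rep(1, half), drop = FALSE], m,
             m[, rep(ncol(m), half), drop = FALSE])
  m <- t(apply(m, 1, function(row) stats::filter(row, w, sides = 2)))
  m[, (half + 1):(half + ncol(mat)), drop = FALSE]
}

# ground-truth ROI fraction implied by a candidate artifact layout
roi_fraction <- function(nr, nc, center, axes, cerumen, hair, defocus) {
  mask <- ellipse_mask(nr, nc, center, axes)
  for (b in cerumen) mask <- mask & !ellipse_mask(nr, nc, b$center, b$radii)
  for (h in hair) mask <- mask & !hair_mask(nr, nc, h$point, h$angle, h$halfwidth)
  if (!is.null(defocus))
    mask[max(1L, defocus[1] + 1L):min(nr, defocus[2]), ] <- FALSE
  mask[c(seq_len(BORDER_PX), nr - seq_len(BORDER_PX) + 1L), ] <- FALSE
  mask[, c(seq_len(BORDER_PX), nc - seq_len(BORDER_PX) + 1L)] <- FALSE
  mean(mask)
}

ellipse_mask <- function(nr, nc, center, axes) {
  r <- matrix(seq_len(nr) - 1, nr, nc)
  c_ <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

hair_mask <- function(nr, nc, point, angle, halfwidth) {
  r <- matrix(seq_len(nr) - 1, nr, nc)
  c_ <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  # distance from the line through `point` with direction (cos, sin)
  d <- abs(-sin(angle) * (r - point[1]) + cos(angle) * (c_ - point[2]))
  d <= halfwidth
}

# AR(1) gain at frame t for an ear, deterministic in (ear seed, t) and
# independent of the order frames are rendered in.
flicker_gain <- function(ear, t, rho, sdev) {
  if (sdev <= 0) return(1)
  with_seed(derive_seed(ear$seed, 1L, salt = 2L), {
    z <- rnorm(t + 1L)
    e <- z[1] * sdev
    for (k in seq_len(t)) e <- rho * e + sqrt(1 - rho^2) * sdev * z[k + 1L]
    1 + e
  })
}

BORDER_PX <- 6L       # unlit sensor border, never part of the ROI
BACKGROUND_LEVEL <- 300
READ_NOISE_SD <- 60

#' Render one synthetic frame and its ground-truth ROI mask
#'
#' Composites, in order: dark background, the elliptical membrane disc
#' (baseline x radial vignette + smooth texture, scaled by the AR(1) flicker
#' gain of `frame_index`), cerumen blobs and hair strokes (dark), an
#' out-of-focus band (heavy blur), the unlit border, and sensor read noise.
#' The ground-truth ROI is the membrane disc minus every artifact, defocus
#' and border pixel.
#'
#' @param ear one element of [sample_cohort()].
#' @param frame_index 0-based position within the ear's clip.
#' @param config the [synthetic_config()] the cohort was sampled from.
#' @return `list(frame = swir_frame, mask = roi_mask)`.
#' @export
render_frame <- function(ear, frame_index, config) {
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  gain <- flicker_gain(ear, frame_index, config$flicker_rho, config$flicker_sd)
  with_seed(derive_seed(ear$seed, frame_index + 1L, salt = 3L), {
    disc <- ellipse_mask(nr, nc, ear$center, ear$axes)
    r <- matrix(seq_len(nr) - 1, nr, nc)
    c_ <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    rad2 <- ((r - ear$center[1]) / ear$axes[1])^2 +
      ((c_ - ear$center[2]) / ear$axes[2])^2
    vig <- 1 - ear$vignette * pmin(rad2, 1)
    texture <- if (ear$texture_sd > 0) {
      coarse <- matrix(rnorm(ceiling(nr / 16) * ceiling(nc / 16)),
                       ceiling(nr / 16), ceiling(nc / 16))
      resize_bilinear(coarse, nr, nc) * ear$texture_sd
    } else matrix(0, nr, nc)
    img <- matrix(BACKGROUND_LEVEL, nr, nc)
    img[disc] <- (ear$baseline * vig[disc] + texture[disc]) * gain
    artifact <- matrix(FALSE, nr, nc)
    for (b in ear$cerumen) {
      foot <- ellipse_mask(nr, nc, b$center, b$radii)
      img[foot] <- b$level
      artifact <- artifact | foot
    }
    for (h in ear$hair) {
      foot <- hair_mask(nr, nc, h$point, h$angle, h$halfwidth)
      img[foot] <- h$level
      artifact <- artifact | foot
    }
    defocus <- matrix(FALSE, nr, nc)
    if (!is.null(ear$defocus)) {
      rows <- seq(max(1L, ear$defocus[1] + 1L), min(nr, ear$defocus[2]))
      blurred <- box_blur(img, 31L)
      img[rows, ] <- blurred[rows, ]
      defocus[rows, ] <- TRUE
    }
    border <- matrix(FALSE, nr, nc)
    border[c(seq_len(BORDER_PX), nr - seq_len(BORDER_PX) + 1L), ] <- TRUE
    border[, c(seq_len(BORDER_PX), nc - seq_len(BORDER_PX) + 1L)] <- TRUE
    img[border] <- BACKGROUND_LEVEL / 3
    if (READ_NOISE_SD > 0) img <- img + rnorm(nr * nc, 0, READ_NOISE_SD)
    img <- round(pmin(pmax(img, 0), MAX_COUNT))
    mask <- disc & !artifact & !defocus & !border
    if (mean(mask) < 0.10)
      stop("ground-truth ROI below 10% of the frame for ear ", ear$ear_id)
    list(frame = swir_frame(img, ear$patient_id, ear$ear_id,
                            ear$frame_start + frame_index, ear$label),
         mask = roi_mask(mask, provenance = "truth"))
  })
}

#' Generate and write a full synthetic dataset
#'
#' Renders one clip of consecutive frames per ear, writes frames and
#' ground-truth masks as PGM under `outdir`, and writes `manifest.csv`.
#' Identical `config` (including seed) reproduces a byte-identical dataset.
#'
#' @param config a [synthetic_config()].
#' @param outdir writable output directory (created if missing).
#' @return The manifest `data.frame`, invisibly the path written.
#' @export
generate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ears <- sample_cohort(config)
  rows <- vector("list", length(ears))
  for (i in seq_along(ears)) {
    ear <- ears[[i]]
    fp <- mp <- character(ear$n_frames)
    for (t in seq_len(ear$n_frames) - 1L) {
      fm <- render_frame(ear, t, config)
      fp[t + 1L] <- file.path(outdir, sprintf("%s_f%03d.pgm", ear$ear_id,
                                              ear$frame_start + t))
      mp[t + 1L] <- file.path(outdir, sprintf("%s_f%03d_mask.pgm", ear$ear_id,
                                              ear$frame_start + t))
      write_frame(fm$frame, fp[t + 1L])
      write_mask(fm$mask, mp[t + 1L])
    }
    rows[[i]] <- data.frame(
      frame_path = fp, mask_path = mp,
      patient_id = ear$patient_id, ear_id = ear$ear_id,
      frame_index = ear$frame_start + seq_len(ear$n_frames) - 1L,
      label = ear$label,
      subset_tag = if (ear$n_frames >= 20L && ear$n_frames <= 22L)
        "frame_range" else "other",
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  frac <- mean(manifest$label == "effusion")
  if (abs(frac - config$prevalence) > 0.03)
    warning(sprintf("frame-level effusion fraction %.3f departs from the %.2f prevalence by more than 3 points",
                    frac, config$prevalence))
  # CSV holds paths relative to its own directory so the dataset (and its
  # bytes) are independent of where it is generated
  rel <- manifest
  rel$frame_path <- basename(rel$frame_path)
  rel$mask_path <- basename(rel$mask_path)
  write_manifest(rel, file.path(outdir, "manifest.csv"))
  manifest
}
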