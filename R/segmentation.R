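# ROI segmentation: five classical baselines plus a trainable two-class
# encoder-decoder semantic segmenter.
#
# The classical methods are intentionally conservative at their defaults:
# in practice they find pixels that are definitely *outside* the focused
# membrane (dark surround, low-variance blur) far more reliably than they
# recover the whole ROI, so they tend to be highly specific but not very
# sensitive. The trainable segmenter is the route that achieves both.

CLASSICAL_METHODS <- c("static_threshold", "adaptive_threshold", "kmeans",
                       "hough_circle", "active_contour", "blur_detect")

#' Classical ROI segmentation baselines
#'
#' @param frame a [swir_frame()] or numeric matrix of counts.
#' @param method one of `"static_threshold"`, `"adaptive_threshold"`,
#'   `"kmeans"`, `"hough_circle"`, `"active_contour"`, `"blur_detect"`.
#' @param params method parameters (all optional):
#'   * `static_threshold`: `thr` (counts, default 8000) — ROI is `v > thr`.
#'   * `adaptive_threshold`: `window` (odd, default 51), `offset`
#'     (counts above the local mean, default 400).
#'   * `kmeans`: `k` (>= 2, default 4); Lloyd iterations on the intensity
#'     histogram with quantile-spaced initial centers (deterministic); ROI
#'     is the brightest cluster.
#'   * `hough_circle`: `downscale` (default 4), `radii` (candidate radius
#'     fractions of the short side, default `seq(0.25, 0.45, by = 0.05)`),
#'     `floor` (counts, default 2000) intersected with the circle.
#'   * `active_contour`: region-competition iterations in the style of a
#'     two-phase level set: `iters` (default 12), `margin` (default 0.2) —
#'     a pixel joins the foreground only if clearly closer to the
#'     foreground mean, biasing toward specificity.
#'   * `blur_detect`: `window` (default 15), `min_sd` (counts, default 150),
#'     `floor` (counts, default 2000) — pixels whose local standard
#'     deviation falls below `min_sd` (defocused or flat) are excluded from
#'     the ROI, as are unlit pixels below `floor`.
#' @return An [roi_mask()] with provenance `"classical:<method>"`.
#' @export
segment_classical <- function(frame, method, params = list()) {
  method <- match.arg(method, CLASSICAL_METHODS)
  px <- if (inherits(frame, "swir_frame")) frame$pixels else as.matrix(frame)
  p <- params
  mask <- switch(method,
    static_threshold = {
      thr <- p$thr %||% 8000
      stopifnot(thr >= 0, thr <= MAX_COUNT)
      px > thr
    },
    adaptive_threshold = {
      win <- as.integer(p$window %||% 51L)
      if (win %% 2L == 0L) stop("window must be odd")
      off <- p$offset %||% 400
      px > box_blur(px, win) + off
    },
    kmeans = {
      k <- as.integer(p$k %||% 4L)
      if (k < 2L) stop("k must be >= 2")
      kmeans_intensity(px, k)
    },
    hough_circle = {
      hough_disc(px, downscale = as.integer(p$downscale %||% 4L),
                 radii = p$radii %||% seq(0.25, 0.45, by = 0.05),
                 floor_thr = p$floor %||% 2000)
    },
    active_contour = {
      region_compete(px, iters = as.integer(p$iters %||% 12L),
                     margin = p$margin %||% 0.2)
    },
    blur_detect = {
      win <- as.integer(p$window %||% 15L)
      min_sd <- p$min_sd %||% 150
      local_sd(px, win) >= min_sd & px > (p$floor %||% 2000)
    })
  roi_mask(mask, provenance = paste0("classical:", method))
}

# deterministic 1-D k-means on intensities: quantile-spaced init, Lloyd on
# the value histogram (equivalent to Lloyd on pixels, far cheaper)
kmeans_intensity <- function(px, k, iters = 50L) {
  v <- sort(unique(as.vector(px)))
  cnt <- tabulate(match(as.vector(px), v), length(v))
  if (length(v) == 1L) return(matrix(TRUE, nrow(px), ncol(px)))
  centers <- sapply(seq_len(k), function(i) roi_quantile(as.vector(px), (i - 1) / (k - 1)))
  centers <- sort(unique(centers))
  if (length(centers) < k) centers <- seq(min(v), max(v), length.out = k)
  for (it in seq_len(iters)) {
    cuts <- c(-Inf, (centers[-length(centers)] + centers[-1]) / 2, Inf)
    assign <- findInterval(v, cuts, rightmost.closed = TRUE)
    new_centers <- vapply(seq_len(k), function(j) {
      sel <- assign == j
      if (any(sel)) sum(v[sel] * cnt[sel]) / sum(cnt[sel]) else centers[j]
    }, 0)
    if (all(abs(new_centers - centers) < 1e-9)) { centers <- new_centers; break }
    centers <- new_centers
  }
  cuts <- c(-Inf, (centers[-length(centers)] + centers[-1]) / 2, Inf)
  matrix(findInterval(as.vector(px), cuts, rightmost.closed = TRUE) == k,
         nrow(px), ncol(px))
}

local_sd <- function(px, win) {
  m <- box_blur(px, win)
  m2 <- box_blur(px^2, win)
  sqrt(pmax(m2 - m^2, 0))
}

# circle vote on a downscaled gradient map; the winning disc is intersected
# with a low static floor so dark artifacts inside the circle stay excluded
hough_disc <- function(px, downscale, radii, floor_thr) {
  small <- resize_nearest(px, nrow(px) %/% downscale, ncol(px) %/% downscale)
  gr <- abs(small[-1, ] - small[-nrow(small), ])[, -1] +
        abs(small[, -1] - small[, -ncol(small)])[-1, ]
  thr <- roi_quantile(as.vector(gr), 0.92)
  er <- which(gr >= thr, arr.ind = TRUE)
  nr <- nrow(small); nc <- ncol(small)
  rads <- round(radii * min(nr, nc))
  best <- c(score = -1, r = nr / 2, c = nc / 2, rad = rads[1])
  centers_r <- seq(round(nr * 0.3), round(nr * 0.7), by = 2)
  centers_c <- seq(round(nc * 0.3), round(nc * 0.7), by = 2)
  for (rad in rads) {
    for (cr in centers_r) for (ccc in centers_c) {
      d <- sqrt((er[, 1] - cr)^2 + (er[, 2] - ccc)^2)
      score <- sum(abs(d - rad) <= 1.5)
      if (score > best["score"]) best <- c(score = score, r = cr, c = ccc, rad = rad)
    }
  }
  r <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  c_ <- matrix(rep(seq_len(ncol(px)), each = nrow(px)), nrow(px), ncol(px))
  circle <- ((r - best["r"] * downscale)^2 + (c_ - best["c"] * downscale)^2) <=
    (best["rad"] * downscale)^2
  circle & (px > floor_thr)
}

# two-phase region competition (active-contour-without-edges flavour):
# alternate mean estimation and biased reassignment, with a smoothing vote
region_compete <- function(px, iters, margin) {
  fg <- px > mean(px)
  if (!any(fg) || all(fg)) return(px > mean(px))
  for (it in seq_len(iters)) {
    c1 <- mean(px[fg]); c0 <- mean(px[!fg])
    if (!is.finite(c1) || !is.finite(c0) || c1 == c0) break
    # join foreground only when clearly closer to its mean
    new_fg <- abs(px - c1) < margin * abs(px - c0)
    smooth <- box_blur(new_fg * 1, 9L) > 0.5
    if (identical(smooth, fg)) { fg <- smooth; break }
    fg <- smooth
  }
  fg
}

# ---- trainable encoder-decoder ---------------------------------------------

#' Segmenter training configuration
#'
#' Mirrors the reference training recipe: 128 x 160 inputs, encoder depth 3,
#' SGD with momentum 0.9, random +/-15-pixel translation augmentation, 20%
#' validation split. The desk defaults (5 epochs, base width 8) keep a
#' CPU-only run in minutes; `epochs = 60` reproduces the full-scale recipe.
#'
#' @param input_shape `(rows, cols)` the network operates at (default
#'   `c(128, 160)`); frames are resized bilinearly on the way in and the
#'   predicted mask is resized back nearest-neighbor.
#' @param encoder_depth number of down/up-sampling stages (default 3).
#' @param base_width channels of the first encoder stage, doubled per stage
#'   (default 8; desk scale).
#' @param epochs training epochs (desk default 5; full-scale 60).
#' @param lr learning rate (default 0.003).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param augment_px translation amplitude in pixels, each direction
#'   (default 15; 0 disables augmentation).
#' @param validation_fraction held-out fraction of the training frames
#'   (default 0.20).
#' @param seed RNG seed for weight init, shuffling and augmentation.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(input_shape = c(128L, 160L), encoder_depth = 3L,
                       base_width = 8L, epochs = 5L, lr = 0.003,
                       momentum = 0.9, augment_px = 15L,
                       validation_fraction = 0.20, seed = 1L) {
  cfg <- list(input_shape = as.integer(input_shape),
              encoder_depth = as.integer(encoder_depth),
              base_width = as.integer(base_width),
              epochs = as.integer(epochs), lr = lr, momentum = momentum,
              augment_px = as.integer(augment_px),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$encoder_depth >= 1L, cfg$base_width >= 1L, cfg$epochs >= 1L,
            cfg$augment_px >= 0L,
            cfg$validation_fraction > 0, cfg$validation_fraction < 1,
            all(cfg$input_shape %% 2L^cfg$encoder_depth == 0L))
  class(cfg) <- "seg_config"
  cfg
}

# op list describing the encoder-decoder; He-initialized with R's RNG
build_segnet_ops <- function(cfg) {
  conv3 <- function(cin, cout) list(
    type = "conv3",
    W = matrix(rnorm(cin * 9 * cout, 0, sqrt(2 / (cin * 9))), cin * 9, cout),
    b = rep(0, cout))
  conv1 <- function(cin, cout) list(
    type = "conv1",
    W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
    b = rep(0, cout))
  relu <- list(type = "relu"); pool <- list(type = "pool"); up <- list(type = "up")
  widths <- cfg$base_width * 2L^(seq_len(cfg$encoder_depth) - 1L)
  ops <- list()
  cin <- 1L
  for (d in seq_len(cfg$encoder_depth)) {
    ops <- c(ops, list(conv3(cin, widths[d]), relu,
                       conv3(widths[d], widths[d]), relu, pool))
    cin <- widths[d]
  }
  for (d in rev(seq_len(cfg$encoder_depth))) {
    cout <- if (d > 1L) widths[d - 1L] else widths[1L]
    ops <- c(ops, list(up, conv3(cin, cout), relu,
                       conv3(cout, cout), relu))
    cin <- cout
  }
  c(ops, list(conv1(cin, 2L)))
}

prep_seg_input <- function(frame, shape) {
  px <- if (inherits(frame, "swir_frame")) frame$pixels else as.matrix(frame)
  resize_bilinear(px, shape[1], shape[2]) / MAX_COUNT
}

#' Train the semantic ROI segmenter
#'
#' A two-class encoder-decoder trained from random initialization with
#' per-pixel cross-entropy, SGD + momentum, and random translation
#' augmentation. A `validation_fraction` of the frames is held out and
#' scored (pixel accuracy) after every epoch.
#'
#' @param frames list of [swir_frame()]s (or matrices), at least 20.
#' @param masks list of aligned [roi_mask()]s (0/1, same shapes).
#' @param config a [seg_config()].
#' @return A `seg_model`: the trained ops, the config, and `log` — a
#'   data.frame with per-epoch `train_acc` and `val_acc`.
#' @export
train_segmenter <- function(frames, masks, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  n <- length(frames)
  if (n == 0L) stop("empty dataset")
  if (n < 20L) stop("need at least 20 frames to train the segmenter")
  if (length(masks) != n) stop("frames and masks are not aligned")
  shp <- config$input_shape
  imgs <- lapply(frames, prep_seg_input, shape = shp)
  msks <- lapply(masks, function(m) {
    m <- unclass(m)
    if (!all(m %in% c(0L, 1L))) stop("masks must contain only 0 and 1")
    resize_nearest(matrix(as.integer(m), nrow(m), ncol(m)), shp[1], shp[2])
  })
  with_seed(config$seed, {
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample(n, n_val)
    ops <- build_segnet_ops(config)
    fit <- .train_segnet_cpp(ops, imgs[-val_idx], msks[-val_idx],
                             imgs[val_idx], msks[val_idx],
                             config$epochs, config$lr, config$momentum,
                             config$augment_px)
    structure(list(ops = fit$ops, config = config,
                   log = data.frame(epoch = seq_len(config$epochs),
                                    train_acc = fit$train_acc,
                                    val_acc = fit$val_acc,
                                    loss = fit$loss)),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model depth=%d width=%d  epochs=%d  final val acc=%.3f>\n",
              x$config$encoder_depth, x$config$base_width, x$config$epochs,
              tail(x$log$val_acc, 1)))
  invisible(x)
}

#' Predict an ROI mask with a trained segmenter
#'
#' Per-pixel argmax over the two classes at the network's working
#' resolution, resized back to the frame's native shape by nearest
#' neighbor. An argmax tie is resolved to not-ROI.
#'
#' @param model a `seg_model` from [train_segmenter()].
#' @param frame a [swir_frame()] or numeric matrix.
#' @return An [roi_mask()] with provenance `"semantic"`.
#' @export
predict_mask <- function(model, frame) {
  stopifnot(inherits(model, "seg_model"))
  px <- if (inherits(frame, "swir_frame")) frame$pixels else as.matrix(frame)
  img <- prep_seg_input(px, model$config$input_shape)
  pred <- .predict_segnet_cpp(model$ops, img)
  roi_mask(resize_nearest(pred, nrow(px), ncol(px)), provenance = "semantic")
}

#' Save / load a segmenter checkpoint
#'
#' The checkpoint embeds the [seg_config()] alongside the weights.
#' @param model a `seg_model`.
#' @param path checkpoint file path.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}

#' Compare a predicted mask against a reference
#'
#' `pixel_accuracy` is the fraction of agreeing pixels; `dice` is
#' `2|P n T| / (|P| + |T|)`; `roi_sensitivity` is the fraction of reference
#' ROI pixels recovered and `roi_specificity` the fraction of non-ROI pixels
#' recovered. If both masks are empty, `dice` and `roi_sensitivity` are 1 by
#' convention (0 if only the reference is empty).
#'
#' @param pred,truth [roi_mask()]s (or 0/1 matrices) of the same shape.
#' @return Named numeric vector of the four metrics, all in \[0, 1\].
#' @export
evaluate_masks <- function(pred, truth) {
  p <- unclass(pred) == 1L; t_ <- unclass(truth) == 1L
  if (!all(dim(p) == dim(t_))) stop("mask shapes differ")
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_); tn <- sum(!p & !t_)
  dice <- if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  sens <- if (tp + fn == 0L) { if (fp == 0L) 1 else 0 } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) 1 else tn / (tn + fp)
  c(pixel_accuracy = (tp + tn) / length(p), dice = dice,
    roi_sensitivity = sens, roi_specificity = spec)
}
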