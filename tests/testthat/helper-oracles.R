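# Independent brute-force oracles. Deliberately scalar/loop-based and kept
# apart from the package's vectorized implementations.

# PNPOLY point-in-polygon (even-odd, half-open crossings), one point at a time
oracle_point_in_poly <- function(py, px_, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 1] > py) != (poly[j, 1] > py)) {
      xint <- (poly[j, 2] - poly[i, 2]) * (py - poly[i, 1]) /
        (poly[j, 1] - poly[i, 1]) + poly[i, 2]
      if (px_ < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(ann, shape) {
  out <- matrix(0L, shape[1], shape[2])
  for (r in seq_len(shape[1]) - 1L) {
    for (cc in seq_len(shape[2]) - 1L) {
      inc <- FALSE; exc <- FALSE
      for (k in seq_along(ann$polygons)) {
        hit <- oracle_point_in_poly(r, cc, ann$polygons[[k]])
        if (hit && ann$polarity[k] == "include") inc <- TRUE
        if (hit && ann$polarity[k] == "exclude") exc <- TRUE
      }
      out[r + 1L, cc + 1L] <- as.integer(inc && !exc)
    }
  }
  out
}

# quantile at rank h = (n-1)q, written as a convex combination of the two
# bracketing order statistics
oracle_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h); hi <- ceiling(h)
  s[lo + 1] * (1 - (h - lo)) + s[hi + 1] * (h - lo)
}

# naive loop-based computation of all 11 ROI statistics
oracle_features <- function(v) {
  n <- length(v)
  msum <- 0; for (x in v) msum <- msum + x
  med <- oracle_quantile(v, 0.5)
  q1 <- oracle_quantile(v, 0.25)
  q3 <- oracle_quantile(v, 0.75)
  sub_mean <- function(keep) {
    s <- 0; k <- 0
    for (x in v) if (keep(x)) { s <- s + x; k <- k + 1 }
    if (k == 0) med else s / k
  }
  sub_median <- function(keep) {
    sub <- c(); for (x in v) if (keep(x)) sub <- c(sub, x)
    if (length(sub) == 0) med else oracle_quantile(sub, 0.5)
  }
  mx <- v[1]; mn <- v[1]
  for (x in v) { if (x > mx) mx <- x; if (x < mn) mn <- x }
  c(mean_intensity = msum / n,
    median_intensity = med,
    mean_iqr = sub_mean(function(x) x >= q1 && x <= q3),
    median_iqr = sub_median(function(x) x >= q1 && x <= q3),
    mean_above = sub_mean(function(x) x > med),
    median_above = sub_median(function(x) x > med),
    mean_below = sub_mean(function(x) x < med),
    median_below = sub_median(function(x) x < med),
    diff_max_median = mx - med,
    diff_median_min = med - mn,
    iqr = q3 - q1)
}

# Mann-Whitney AUC: P(s+ > s-) + P(s+ = s-)/2 by explicit pairwise count
oracle_auc <- function(scores, truth) {
  sp <- scores[truth == "effusion"]
  sn <- scores[truth == "no_effusion"]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "effusion") {
      if (pred[i] == "effusion") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == "no_effusion") tn <- tn + 1 else fp <- fp + 1
    }
  }
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2)
}

oracle_mask_metrics <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == 1; t_ <- truth[i] == 1
    if (p && t_) tp <- tp + 1
    if (p && !t_) fp <- fp + 1
    if (!p && t_) fn <- fn + 1
    if (!p && !t_) tn <- tn + 1
  }
  c(pixel_accuracy = (tp + tn) / length(pred),
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    roi_sensitivity = if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn),
    roi_specificity = if (tn + fp == 0) 1 else tn / (tn + fp))
}

# small cohort configuration for fast end-to-end tests (overridable defaults)
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_ears = 8L, frames_per_ear = c(3L, 4L),
                                 frame_shape = c(64L, 80L)), list(...))
  do.call(synthetic_config, args)
}

rect_poly <- function(r0, c0, r1, c1) {
  rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
}
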