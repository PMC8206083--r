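# ROI intensity parameterization.
#
# Input Set 1 is the average intensity inside the ROI. Input Set 2 is the
# full 11-statistic set: mean and median; mean and median of the pixels
# inside the interquartile range; mean and median of the pixels strictly
# above (and strictly below) the median; and the three intensity differences
# maximum-to-median, median-to-minimum, and the IQR itself. All statistics
# are global over the entire ROI, never over subsections.

FEATURE_NAMES <- c("mean_intensity", "median_intensity",
                   "mean_iqr", "median_iqr",
                   "mean_above", "median_above",
                   "mean_below", "median_below",
                   "diff_max_median", "diff_median_min", "iqr")

#' Linear-interpolation quantile
#'
#' The quantile convention used throughout the package (and by its tests'
#' independent oracle): sort the values and linearly interpolate the order
#' statistics at rank `h = (n - 1) * q` (0-based).
#'
#' @param values nonempty numeric vector.
#' @param q fraction in \[0, 1\].
#' @return The interpolated quantile.
#' @export
roi_quantile <- function(values, q) {
  if (length(values) == 0L) stop("empty value list")
  stopifnot(q >= 0, q <= 1)
  s <- sort(values)
  h <- (length(s) - 1) * q
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

#' Extract ROI intensity features from one frame
#'
#' Statistics are computed over the multiset of pixel values inside the
#' mask only. "Above"/"below" subsets use strict inequality against the
#' median; the IQR subset uses inclusive bounds `Q1 <= v <= Q3`. A subset
#' left empty by ties collapses to the median intensity (fallback), so every
#' field is defined even for a constant ROI.
#'
#' @param frame a [swir_frame()] (or a bare numeric matrix).
#' @param mask an [roi_mask()] of the same shape with at least one ROI pixel.
#' @param input_set `"set1"` (mean intensity only) or `"set2"` (all 11).
#' @return Named numeric vector: 1 field for set1, 11 for set2.
#' @export
extract_features <- function(frame, mask, input_set = c("set2", "set1")) {
  input_set <- match.arg(input_set)
  px <- if (inherits(frame, "swir_frame")) frame$pixels else as.matrix(frame)
  if (!all(dim(px) == dim(mask))) stop("frame and mask shapes differ")
  v <- px[unclass(mask) == 1L]
  if (length(v) == 0L) stop("empty ROI")
  if (input_set == "set1") return(c(mean_intensity = mean(v)))
  med <- roi_quantile(v, 0.5)
  q1 <- roi_quantile(v, 0.25)
  q3 <- roi_quantile(v, 0.75)
  in_iqr <- v[v >= q1 & v <= q3]
  above <- v[v > med]
  below <- v[v < med]
  stat_or_med <- function(x, f) if (length(x)) f(x) else med
  med_of <- function(x) roi_quantile(x, 0.5)
  c(mean_intensity = mean(v),
    median_intensity = med,
    mean_iqr = stat_or_med(in_iqr, mean),
    median_iqr = stat_or_med(in_iqr, med_of),
    mean_above = stat_or_med(above, mean),
    median_above = stat_or_med(above, med_of),
    mean_below = stat_or_med(below, mean),
    median_below = stat_or_med(below, med_of),
    diff_max_median = max(v) - med,
    diff_median_min = med - min(v),
    iqr = q3 - q1)
}

#' Featurize a whole dataset
#'
#' One feature row per manifest frame, in manifest order. Frames whose mask
#' has no ROI pixel are dropped with a warning reporting how many.
#'
#' @param manifest manifest `data.frame` (see [read_manifest()]); its
#'   `frame_path`/`mask_path` columns are read from disk unless `frames` and
#'   `masks` are supplied.
#' @param masks optional named list of [roi_mask()]s keyed
#'   `"<ear_id>_<frame_index>"`, overriding the manifest's mask files (e.g.
#'   predictions from [predict_mask()]).
#' @param input_set `"set1"` or `"set2"`.
#' @param frames optional named list of [swir_frame()]s with the same keys.
#' @return A feature table: `data.frame` with identifier columns
#'   (`patient_id`, `ear_id`, `frame_index`, `label`), the feature columns,
#'   and attribute `input_set`.
#' @export
featurize_dataset <- function(manifest, masks = NULL,
                              input_set = c("set2", "set1"), frames = NULL) {
  input_set <- match.arg(input_set)
  keys <- paste(manifest$ear_id, manifest$frame_index, sep = "_")
  rows <- vector("list", nrow(manifest))
  dropped <- 0L
  for (i in seq_len(nrow(manifest))) {
    fr <- if (!is.null(frames)) frames[[keys[i]]]
          else read_frame(manifest$frame_path[i])
    mk <- if (!is.null(masks)) masks[[keys[i]]]
          else {
            if (is.na(manifest$mask_path[i]) || !nzchar(manifest$mask_path[i]))
              stop("missing mask for frame ", keys[i])
            read_mask(manifest$mask_path[i])
          }
    if (is.null(mk)) stop("missing mask for frame ", keys[i])
    if (sum(unclass(mk)) == 0L) { dropped <- dropped + 1L; next }
    rows[[i]] <- c(extract_features(fr, mk, input_set))
  }
  if (dropped > 0L)
    warning(dropped, " frame(s) dropped: empty ROI mask")
  keep <- !vapply(rows, is.null, TRUE)
  feat <- as.data.frame(do.call(rbind, rows[keep]))
  out <- cbind(manifest[keep, c("patient_id", "ear_id", "frame_index", "label")],
               feat, row.names = NULL)
  attr(out, "input_set") <- input_set
  out
}

#' Render a synthetic cohort and featurize it in one pass
#'
#' Streams frame rendering into feature extraction so a full cohort (about
#' 1100-1200 frames at sensor geometry) never needs to be held in memory or
#' written to disk. Ground-truth ROI masks are used.
#'
#' @param config a [synthetic_config()].
#' @param input_set `"set1"` or `"set2"`.
#' @return A feature table as in [featurize_dataset()].
#' @export
cohort_features <- function(config, input_set = c("set2", "set1")) {
  input_set <- match.arg(input_set)
  ears <- sample_cohort(config)
  rows <- vector("list", length(ears))
  for (i in seq_along(ears)) {
    ear <- ears[[i]]
    er <- vector("list", ear$n_frames)
    for (t in seq_len(ear$n_frames) - 1L) {
      fm <- render_frame(ear, t, config)
      er[[t + 1L]] <- data.frame(
        patient_id = ear$patient_id, ear_id = ear$ear_id,
        frame_index = ear$frame_start + t, label = ear$label,
        as.list(extract_features(fm$frame, fm$mask, input_set)),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, er)
  }
  out <- do.call(rbind, rows)
  attr(out, "input_set") <- input_set
  out
}

#' Write / read a feature table as CSV
#' @param table feature table from [featurize_dataset()].
#' @param path CSV path.
#' @export
write_features <- function(table, path) {
  df <- cbind(table, input_set = attr(table, "input_set") %||% "set2")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  iset <- unique(df$input_set)
  df$input_set <- NULL
  attr(df, "input_set") <- iset
  df
}
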