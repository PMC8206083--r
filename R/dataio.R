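#' @useDynLib swirotome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rbinom median var sd aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

MAX_COUNT <- 16383L  # 14-bit analog-to-digital full scale

FRAME_LABELS <- c("effusion", "no_effusion", "unknown")

#' Construct a SWIR frame
#'
#' A frame is one 2-D grayscale shortwave-infrared image together with its
#' cohort identifiers and the myringotomy-confirmed effusion label. Pixel
#' values are intensity counts on the sensor's 14-bit scale, i.e. in
#' \[0, 16383\].
#'
#' @param pixels numeric matrix of intensity counts; values outside
#'   \[0, 16383\] are an error.
#' @param patient_id,ear_id character identifiers; `ear_id` must be unique
#'   per ear (patient + side).
#' @param frame_index non-negative integer position of the frame in its clip.
#' @param label one of `"effusion"`, `"no_effusion"`, `"unknown"`.
#' @return An object of class `swir_frame`.
#' @export
swir_frame <- function(pixels, patient_id = "NA", ear_id = "NA",
                       frame_index = 0L, label = "unknown") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("frame pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > MAX_COUNT)
    stop("frame pixels must lie in [0, ", MAX_COUNT, "]")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("frame dimensions must be positive")
  label <- match.arg(label, FRAME_LABELS)
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) stop("frame_index must be >= 0")
  structure(list(pixels = pixels,
                 patient_id = as.character(patient_id),
                 ear_id = as.character(ear_id),
                 frame_index = frame_index,
                 label = label),
            class = "swir_frame")
}

#' @export
print.swir_frame <- function(x, ...) {
  cat(sprintf("<swir_frame %s/%s #%d  %dx%d  label=%s  range=[%d,%d]>\n",
              x$patient_id, x$ear_id, x$frame_index,
              nrow(x$pixels), ncol(x$pixels), x$label,
              as.integer(min(x$pixels)), as.integer(max(x$pixels))))
  invisible(x)
}

#' Construct an ROI mask
#'
#' Binary per-pixel membership in the focused, artifact-free portion of the
#' tympanic membrane. Class 1 = ROI, class 0 = not-ROI.
#'
#' @param mask matrix coercible to 0/1 integer.
#' @param provenance where the mask came from: `"annotation"`, `"semantic"`,
#'   `"truth"`, or `"classical:<method>"`.
#' @return Integer 0/1 matrix of class `roi_mask` with a `provenance`
#'   attribute.
#' @export
roi_mask <- function(mask, provenance = "annotation") {
  mask <- as.matrix(mask)
  if (is.logical(mask)) storage.mode(mask) <- "integer"
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  structure(mask, class = c("roi_mask", "matrix", "array"),
            provenance = as.character(provenance))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %dx%d  roi=%d px (%.1f%%)  provenance=%s>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x),
              attr(x, "provenance")))
  invisible(x)
}

# ---- PGM backing store ------------------------------------------------------
# Frames and masks are stored as binary (P5) netpbm PGM: single channel, with
# maxval 16383 (frames, two bytes per pixel, big-endian) or maxval 1 (masks,
# one byte per pixel). The format is lossless for the 14-bit range and needs
# no image library; any netpbm-aware viewer opens it.

write_pgm <- function(mat, path, maxval) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  vals <- as.integer(round(t(mat)))  # row-major, top-left origin
  if (maxval > 255L) {
    raw2 <- raw(2L * length(vals))
    raw2[c(TRUE, FALSE)] <- as.raw(vals %/% 256L)
    raw2[c(FALSE, TRUE)] <- as.raw(vals %% 256L)
    writeBin(raw2, con)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (magic %in% c("P3", "P6"))
    stop("multi-channel input (PPM) is not supported: ", path)
  if (!magic %in% c("P2", "P5"))
    stop("unreadable format (expected PGM): ", path)
  # header tokens: width height maxval, '#' comments allowed
  toks <- integer(0)
  buf <- ""
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header: ", path)
    if (ch == "#") {  # skip comment line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- paste0(buf, ch)
    } else if (nzchar(buf)) {
      toks <- c(toks, as.integer(buf)); buf <- ""
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (maxval > 65535L) stop("bit depth above 16 not supported: ", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval > 255L) {
    raw2 <- readBin(con, "raw", 2L * n)
    vals <- as.integer(raw2[c(TRUE, FALSE)]) * 256L + as.integer(raw2[c(FALSE, TRUE)])
  } else {
    vals <- as.integer(readBin(con, "raw", n))
  }
  if (length(vals) < n) stop("truncated PGM payload: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read a SWIR frame from disk
#'
#' Frames are single-channel PGM images with bit depth up to 16; values are
#' clipped to the 14-bit range \[0, 16383\] on read. `read_frame()` and
#' [write_frame()] round-trip losslessly.
#'
#' @param path file path of a single-channel PGM image.
#' @param patient_id,ear_id,frame_index,label frame metadata (see
#'   [swir_frame()]).
#' @return A `swir_frame`.
#' @export
read_frame <- function(path, patient_id = "NA", ear_id = "NA",
                       frame_index = 0L, label = "unknown") {
  px <- read_pgm(path)
  px[px > MAX_COUNT] <- MAX_COUNT
  swir_frame(px, patient_id, ear_id, frame_index, label)
}

#' Write a SWIR frame to disk
#'
#' @param frame a `swir_frame`.
#' @param path destination path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "swir_frame"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  write_pgm(frame$pixels, path, maxval = MAX_COUNT)
}

#' Read / write an ROI mask
#'
#' Masks are stored as PGM with maxval 1 (one byte per pixel, values 0/1).
#'
#' @param path file path.
#' @param provenance provenance tag attached on read.
#' @return `read_mask()` returns an `roi_mask`; `write_mask()` returns `path`.
#' @export
read_mask <- function(path, provenance = "annotation") {
  m <- read_pgm(path)
  roi_mask(m > 0L, provenance = provenance)
}

#' @rdname read_mask
#' @param mask an `roi_mask` (or 0/1 matrix).
#' @export
write_mask <- function(mask, path) {
  mask <- roi_mask(mask, provenance = attr(mask, "provenance") %||% "annotation")
  write_pgm(unclass(mask), path, maxval = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- polygon annotations ----------------------------------------------------

#' Polygon annotation of a frame
#'
#' Annotations delimit the region of interest by closed polygons: `include`
#' polygons cover the focused tympanic membrane, `exclude` polygons carve out
#' artifacts (cerumen, hair, out-of-focus regions). Vertices are `(row, col)`
#' pairs, 0-based, origin at the top-left pixel, with integer coordinates at
#' pixel centers.
#'
#' @param polygons list of numeric n x 2 matrices (row, col), each with at
#'   least 3 vertices.
#' @param polarity character vector, one of `"include"`/`"exclude"` per
#'   polygon.
#' @param frame optional frame identifier carried through serialization.
#' @return An object of class `swir_annotation`.
#' @export
swir_annotation <- function(polygons, polarity, frame = NA_character_) {
  stopifnot(length(polygons) == length(polarity))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3L) stop("polygon with < 3 vertices")
    if (ncol(p) != 2L) stop("polygon vertices must be (row, col) pairs")
    storage.mode(p) <- "double"
    p
  })
  polarity <- vapply(polarity, match.arg, "", choices = c("include", "exclude"))
  structure(list(frame = frame, polygons = polygons,
                 polarity = unname(polarity)),
            class = "swir_annotation")
}

#' @rdname swir_annotation
#' @param path JSON file `{frame, polygons: [{polarity, vertices: [[row,col],...]}]}`.
#' @export
read_annotation <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(doc$polygons, function(p)
    do.call(rbind, lapply(p$vertices, function(v) as.numeric(unlist(v)))))
  pol <- vapply(doc$polygons, function(p) as.character(p$polarity), "")
  swir_annotation(polys, pol, frame = doc$frame %||% NA_character_)
}

#' @rdname swir_annotation
#' @param ann a `swir_annotation`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "swir_annotation"))
  doc <- list(
    frame = ann$frame,
    polygons = Map(function(p, pol) {
      list(polarity = pol,
           vertices = lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ])))
    }, ann$polygons, ann$polarity))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd ray casting at pixel centers. Points are (row, col), 0-based.
# A point on an edge follows the half-open crossing rule (consistent, no
# double counting between polygons sharing an edge).
point_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  vr <- poly[, 1]; vc <- poly[, 2]
  jr <- c(vr[n], vr[-n]); jc <- c(vc[n], vc[-n])
  inside <- rep(FALSE, length(pr))
  for (k in seq_len(n)) {
    crosses <- ((vr[k] > pr) != (jr[k] > pr))
    if (any(crosses)) {
      xc <- jc[k] + (pr[crosses] - jr[k]) / (vr[k] - jr[k]) * (vc[k] - jc[k])
      flip <- pc[crosses] < xc
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

#' Rasterize a polygon annotation to an ROI mask
#'
#' The mask is the union of the include polygons minus the union of the
#' exclude polygons. A pixel belongs to a polygon when its center (integer
#' (row, col), 0-based, top-left origin) falls inside the polygon by the
#' even-odd rule.
#'
#' @param ann a `swir_annotation`.
#' @param shape integer `(rows, cols)` of the target frame.
#' @return An `roi_mask` with provenance `"annotation"`.
#' @export
rasterize_annotation <- function(ann, shape) {
  stopifnot(inherits(ann, "swir_annotation"), length(shape) == 2L, all(shape >= 1))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  pr <- rep(0:(nr - 1L), times = nc)   # column-major grid of pixel centers
  pc <- rep(0:(nc - 1L), each = nr)
  inc <- rep(FALSE, nr * nc); exc <- rep(FALSE, nr * nc)
  for (k in seq_along(ann$polygons)) {
    hit <- point_in_polygon(pr, pc, ann$polygons[[k]])
    if (ann$polarity[k] == "include") inc <- inc | hit else exc <- exc | hit
  }
  roi_mask(matrix(inc & !exc, nr, nc), provenance = "annotation")
}

# ---- cohort manifest --------------------------------------------------------

MANIFEST_COLS <- c("frame_path", "mask_path", "patient_id", "ear_id",
                   "frame_index", "label", "subset_tag")
SUBSET_TAGS <- c("best_frame", "frame_range", "other")

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with header
#' `frame_path,mask_path,patient_id,ear_id,frame_index,label,subset_tag`.
#' Labels must be `effusion` or `no_effusion`; `(ear_id, frame_index)` pairs
#' must be unique. For each ear, `frame_range` rows are expected to form a
#' clip of 20-22 consecutive frame indices; a departure raises a warning, not
#' an error (best-frame-only manifests are legitimate).
#'
#' @param path CSV file path.
#' @param resolve make relative `frame_path`/`mask_path` entries absolute
#'   against the CSV's own directory (default TRUE), so a dataset directory
#'   is relocatable.
#' @return A `data.frame` with the manifest columns.
#' @export
read_manifest <- function(path, resolve = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  m <- validate_manifest(transform(m, frame_index = as.integer(frame_index)))
  if (resolve) {
    root <- dirname(normalizePath(path))
    fix <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                              file.path(root, p), p)
    m$frame_path <- fix(m$frame_path)
    m$mask_path <- fix(m$mask_path)
  }
  m
}

#' @rdname read_manifest
#' @param manifest manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  missing_cols <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  m <- m[, MANIFEST_COLS]
  bad <- setdiff(unique(m$label), c("effusion", "no_effusion"))
  if (length(bad))
    stop("unknown label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels: 'effusion', 'no_effusion'")
  key <- paste(m$ear_id, m$frame_index)
  if (anyDuplicated(key))
    stop("duplicate (ear_id, frame_index): ", key[duplicated(key)][1])
  rng <- m[m$subset_tag == "frame_range", ]
  if (nrow(rng)) {
    for (ear in unique(rng$ear_id)) {
      idx <- sort(rng$frame_index[rng$ear_id == ear])
      consecutive <- all(diff(idx) == 1L)
      if (!consecutive || length(idx) < 20L || length(idx) > 22L)
        warning("ear ", ear, ": frame_range rows are not a clip of 20-22 ",
                "consecutive frames (found ", length(idx), ")", call. = FALSE)
    }
  }
  m
}
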