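# End-to-end orchestration: simulate -> segment -> featurize -> evaluate.
#
# The default pipeline classifies on ground-truth masks and trains/scores
# the semantic segmenter separately, so classifier assessment is not
# confounded by segmentation error; `segmentation_source = "semantic"` (or
# "classical:<method>") routes predicted masks into featurization instead.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()].
#' @param segmenter a [seg_config()].
#' @param splits a [split_spec()].
#' @param cases list of [case_spec()]s (default Cases 1-3).
#' @param segmentation_source mask source for featurization:
#'   `"truth_mask"` (default), `"semantic"`, or `"classical:<method>"`.
#' @param train_segmenter train and score the semantic segmenter as part of
#'   the run (default TRUE when `segmentation_source = "semantic"`,
#'   FALSE otherwise).
#' @param seg_train_frames frames used to train the segmenter (default 100).
#' @param seed global seed; sub-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            segmenter = seg_config(),
                            splits = split_spec(),
                            cases = lapply(1:3, case_spec),
                            segmentation_source = "truth_mask",
                            train_segmenter = NULL,
                            seg_train_frames = 100L,
                            seed = 42L) {
  src_ok <- segmentation_source %in% c("truth_mask", "semantic") ||
    startsWith(segmentation_source, "classical:")
  if (!src_ok) stop("unknown segmentation_source: ", segmentation_source)
  structure(list(synthetic = synthetic, segmenter = segmenter,
                 splits = splits, cases = cases,
                 segmentation_source = segmentation_source,
                 train_segmenter = train_segmenter %||%
                   (segmentation_source == "semantic"),
                 seg_train_frames = as.integer(seg_train_frames),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `synthetic`, `segmenter`, `splits` hold the respective
#' constructor arguments; `cases` is a list of case ids or argument lists;
#' remaining keys are passed to [pipeline_config()] directly.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path) %||% list()
  args <- list()
  if (!is.null(doc$synthetic)) args$synthetic <- do.call(synthetic_config, doc$synthetic)
  if (!is.null(doc$segmenter)) args$segmenter <- do.call(seg_config, doc$segmenter)
  if (!is.null(doc$splits)) args$splits <- do.call(split_spec, doc$splits)
  if (!is.null(doc$cases))
    args$cases <- lapply(doc$cases, function(cs)
      if (is.list(cs)) do.call(case_spec, cs) else case_spec(cs))
  for (k in intersect(names(doc), c("segmentation_source", "train_segmenter",
                                    "seg_train_frames", "seed")))
    args[[k]] <- doc[[k]]
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) sample the synthetic cohort and stream rendered frames into
#' feature extraction, using the configured mask source; (2) optionally
#' train the semantic segmenter on a subset of frames and score it on its
#' validation split; (3) evaluate all configured classification cases by
#' repeated stratified hold-out. A rerun with the same configuration is
#' identical (all randomness derives from `config$seed`).
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, the feature table, the
#'   evaluation report (JSON) and per-iteration metrics (CSV) are written
#'   under it.
#' @return `list(features =, reports =, segmentation =, config =)`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  syn$seed <- derive_seed(config$seed, 1L, salt = 11L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  seg_model <- NULL
  seg_metrics <- NULL
  if (config$train_segmenter ||
      config$segmentation_source == "semantic") {
    seg_model <- stage("segment-train", {
      ears <- sample_cohort(syn)
      frames <- list(); masks <- list()
      for (ear in ears) {
        for (t in seq_len(ear$n_frames) - 1L) {
          fm <- render_frame(ear, t, syn)
          frames[[length(frames) + 1L]] <- fm$frame
          masks[[length(masks) + 1L]] <- fm$mask
          if (length(frames) >= config$seg_train_frames) break
        }
        if (length(frames) >= config$seg_train_frames) break
      }
      cfg <- config$segmenter
      cfg$seed <- derive_seed(config$seed, 2L, salt = 11L)
      train_segmenter(frames, masks, cfg)
    })
    seg_metrics <- utils::tail(seg_model$log, 1L)
  }

  features <- stage("featurize", {
    if (config$segmentation_source == "truth_mask") {
      cohort_features(syn, input_set = "set2")
    } else {
      ears <- sample_cohort(syn)
      rows <- list()
      for (ear in ears) {
        for (t in seq_len(ear$n_frames) - 1L) {
          fm <- render_frame(ear, t, syn)
          mask <- if (config$segmentation_source == "semantic") {
            predict_mask(seg_model, fm$frame)
          } else {
            method <- sub("^classical:", "", config$segmentation_source)
            segment_classical(fm$frame, method)
          }
          if (sum(unclass(mask)) == 0L) next
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = ear$patient_id, ear_id = ear$ear_id,
            frame_index = ear$frame_start + t, label = ear$label,
            as.list(extract_features(fm$frame, mask, "set2")),
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows) == 0L)
        stop("no frame received a nonempty ROI mask from source '",
             config$segmentation_source, "'")
      out <- do.call(rbind, rows)
      attr(out, "input_set") <- "set2"
      out
    }
  })

  reports <- stage("evaluate", {
    sp <- config$splits
    sp$seed <- derive_seed(config$seed, 3L, salt = 11L)
    evaluate_all_cases(features, sp, config$cases)
  })

  result <- list(features = features, reports = reports,
                 segmentation = list(model = seg_model, metrics = seg_metrics),
                 config = config)
  if (!is.null(outdir)) stage("report", write_run_report(result, outdir))
  result
}

write_run_report <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_features(result$features, file.path(outdir, "features.csv"))
  iters <- do.call(rbind, lapply(result$reports, function(r)
    cbind(case_id = r$case_id, r$iterations)))
  utils::write.csv(iters, file.path(outdir, "iterations.csv"),
                   row.names = FALSE)
  summary <- lapply(result$reports, function(r)
    c(as.list(r$means), n_iterations = nrow(r$iterations)))
  seg <- if (!is.null(result$segmentation$metrics))
    as.list(result$segmentation$metrics)
  jsonlite::write_json(
    list(seed = result$config$seed,
         segmentation_source = result$config$segmentation_source,
         segmentation = seg, cases = summary),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(result$reports)) {
    rocs <- result$reports[[nm]]$rocs
    roc_df <- do.call(rbind, lapply(seq_along(rocs), function(i)
      cbind(iteration = i, rocs[[i]])))
    utils::write.csv(roc_df, file.path(outdir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' Command-line entry point
#'
#' Used by the `inst/cli/swirotome` script:
#' `swirotome run-all --config cfg.yaml --seed 42 --out dir/` (also
#' `simulate` and `featurize` subcommands). Exit codes: 0 success, 2
#' configuration error, 3 stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status integer, invisibly.
#' @export
swirotome_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: swirotome <run-all|simulate|featurize> [--config cfg.yaml] [--seed N] [--out dir]"
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(config = NULL, seed = 42L, out = "swirotome_out")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message("bad option: ", args[i], "\n", usage); return(invisible(2L))
    }
    opt[[key]] <- args[i + 1L]; i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  cfg <- tryCatch({
    base <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
            else pipeline_config()
    base$seed <- opt$seed
    base
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(invisible(2L))
  status <- tryCatch({
    switch(cmd,
      "run-all" = {
        res <- run_pipeline(cfg, outdir = opt$out)
        for (r in res$reports) print(r)
        0L
      },
      simulate = {
        syn <- cfg$synthetic; syn$seed <- derive_seed(cfg$seed, 1L, salt = 11L)
        generate_dataset(syn, opt$out)
        0L
      },
      featurize = {
        syn <- cfg$synthetic; syn$seed <- derive_seed(cfg$seed, 1L, salt = 11L)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_features(cohort_features(syn),
                       file.path(opt$out, "features.csv"))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 3L
  })
  invisible(status)
}
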