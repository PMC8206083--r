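# Effusion classification and validation.
#
# Three escalating cases are evaluated by repeated stratified 62/38 hold-out
# validation ("tenfold hold-out cross-validation": ten independent random
# hold-outs, since a 62/38 split is incompatible with ten disjoint folds):
#   Case 1 - decision stump (single threshold) on the mean ROI intensity,
#   Case 2 - decision tree on all 11 intensity statistics,
#   Case 3 - 200-tree random forest on all 11 statistics, class-weighted and
#            threshold-tuned for balanced accuracy.
# The positive class is "effusion" throughout.

#' Hold-out split specification
#'
#' @param n_iterations number of independent random hold-outs (default 10).
#' @param train_fraction fraction assigned to training (default 0.62).
#' @param stratified preserve the class balance on both sides (default TRUE).
#' @param grouping `"ear"` (default; all frames of an ear stay on one side,
#'   preventing leakage between nearly identical frames) or `"frame"`
#'   (frame-level splitting).
#' @param seed RNG seed for the split draws.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(n_iterations = 10L, train_fraction = 0.62,
                       stratified = TRUE, grouping = c("ear", "frame"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  spec <- list(n_iterations = as.integer(n_iterations),
               train_fraction = train_fraction, stratified = stratified,
               grouping = grouping, seed = as.integer(seed))
  stopifnot(spec$n_iterations >= 1L,
            spec$train_fraction > 0, spec$train_fraction < 1)
  class(spec) <- "split_spec"
  spec
}

#' Classification case specification
#'
#' @param case_id 1, 2 or 3. Case 1 fixes `input_set = "set1"` with a
#'   decision stump; Case 2 a depth-unlimited decision tree on `"set2"`;
#'   Case 3 a random forest on `"set2"`.
#' @param n_trees forest size for Case 3 (default 200).
#' @param max_depth tree depth limit (Case 1: 1; Case 2/3 default 30).
#' @param min_leaf minimum training rows per leaf (Case 2 default 5;
#'   Case 3 default 1).
#' @param balanced_optimization Case 3 only (default TRUE): weight classes
#'   by inverse frequency and tune the score threshold on the training set
#'   to maximize balanced accuracy.
#' @return A list of class `case_spec`.
#' @export
case_spec <- function(case_id, n_trees = 200L, max_depth = NULL,
                      min_leaf = NULL, balanced_optimization = NULL) {
  case_id <- as.integer(case_id)
  stopifnot(case_id %in% 1:3)
  spec <- switch(case_id,
    list(case_id = 1L, input_set = "set1", model = "decision_tree",
         n_trees = 1L, max_depth = 1L, min_leaf = 1L,
         balanced_optimization = FALSE),
    list(case_id = 2L, input_set = "set2", model = "decision_tree",
         n_trees = 1L, max_depth = max_depth %||% 30L,
         min_leaf = min_leaf %||% 5L, balanced_optimization = FALSE),
    list(case_id = 3L, input_set = "set2", model = "random_forest",
         n_trees = as.integer(n_trees), max_depth = max_depth %||% 30L,
         min_leaf = min_leaf %||% 1L,
         balanced_optimization = balanced_optimization %||% TRUE))
  class(spec) <- "case_spec"
  spec
}

feature_cols <- function(table, input_set) {
  cols <- if (input_set == "set1") "mean_intensity" else FEATURE_NAMES
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  cols
}

# per-class train counts: round() per class, then largest-remainder
# reconciliation so the overall train size equals round(frac * n)
stratified_counts <- function(class_sizes, frac) {
  exact <- frac * class_sizes
  counts <- round(exact)
  total <- round(frac * sum(class_sizes))
  while (sum(counts) != total) {
    resid <- exact - counts
    if (sum(counts) < total) {
      j <- which.max(resid); counts[j] <- counts[j] + 1L
    } else {
      j <- which.min(resid); counts[j] <- counts[j] - 1L
    }
  }
  pmin(pmax(counts, 1L), class_sizes - 1L)
}

#' Draw repeated stratified hold-out splits
#'
#' Each iteration draws an independent random train/test partition. Under
#' stratification the training side receives `round(train_fraction * n)` of
#' each class (largest-remainder reconciled); under ear grouping the draw is
#' over ears, and every frame follows its ear.
#'
#' @param table feature table ([featurize_dataset()] / [cohort_features()]).
#' @param spec a [split_spec()].
#' @return List of `n_iterations` elements, each `list(train =, test =)`
#'   of row indices into `table`.
#' @export
make_splits <- function(table, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labs <- table$label
  if (length(unique(labs)) < 2L) stop("both classes must be present")
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_iterations), function(it) {
      if (spec$grouping == "ear") {
        ears <- unique(table$ear_id)
        ear_lab <- labs[match(ears, table$ear_id)]
        if (min(table(ear_lab)) < 2L)
          stop("a class has fewer than 2 ears; cannot split by ear")
        train_ears <- character(0)
        if (spec$stratified) {
          for (cl in unique(ear_lab)) {
            cl_ears <- ears[ear_lab == cl]
            n_tr <- stratified_counts(
              structure(length(cl_ears), names = cl), spec$train_fraction)
            train_ears <- c(train_ears, sample(cl_ears, n_tr))
          }
        } else {
          train_ears <- sample(ears, round(spec$train_fraction * length(ears)))
        }
        train <- which(table$ear_id %in% train_ears)
      } else {
        if (spec$stratified) {
          classes <- sort(unique(labs))
          sizes <- vapply(classes, function(cl) sum(labs == cl), 0L)
          counts <- stratified_counts(sizes, spec$train_fraction)
          train <- unlist(lapply(seq_along(classes), function(j)
            sample(which(labs == classes[j]), counts[j])))
        } else {
          train <- sample(seq_along(labs), round(spec$train_fraction * length(labs)))
        }
      }
      list(train = sort(train), test = setdiff(seq_along(labs), sort(train)))
    })
  })
}

#' Fit a classification case
#'
#' Case 1 fits a single-split decision stump on the mean ROI intensity.
#' Case 2 fits a Gini decision tree on all 11 statistics. Case 3 fits a
#' random forest: each of `n_trees` trees is grown on a bootstrap sample of
#' the training rows with `floor(sqrt(p))` features tried per split, and the
#' forest score is the mean of the trees' leaf positive fractions. With
#' balanced optimization, rows are weighted by inverse class frequency and
#' the decision threshold is tuned on the training scores to maximize
#' balanced accuracy; otherwise the threshold is 0.5.
#'
#' @param train training feature table (both classes present).
#' @param case a [case_spec()].
#' @param seed RNG seed (bootstraps, feature subsampling).
#' @return A `case_model` with the fitted trees and decision threshold.
#' @export
fit_case <- function(train, case, seed = 1L) {
  stopifnot(inherits(case, "case_spec"))
  if (nrow(train) == 0L) stop("empty training set")
  y <- as.integer(train$label == "effusion")
  if (length(unique(y)) < 2L) stop("single-class training set")
  cols <- feature_cols(train, case$input_set)
  X <- as.matrix(train[, cols, drop = FALSE])
  w <- if (case$balanced_optimization) {
    ifelse(y == 1L, 0.5 / mean(y == 1L), 0.5 / mean(y == 0L))
  } else rep(1, length(y))
  with_seed(seed, {
    if (case$model == "decision_tree") {
      trees <- list(.grow_tree_cpp(X, y, w, case$max_depth, case$min_leaf, 0L))
    } else {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      trees <- lapply(seq_len(case$n_trees), function(b) {
        idx <- sample(nrow(X), replace = TRUE)
        .grow_tree_cpp(X[idx, , drop = FALSE], y[idx], w[idx],
                       case$max_depth, case$min_leaf, mtry)
      })
    }
    model <- structure(list(case = case, trees = trees, features = cols,
                            threshold = 0.5),
                       class = "case_model")
    if (case$balanced_optimization) {
      sc <- predict_scores(model, train)
      model$threshold <- tune_threshold(sc, y)
    }
    model
  })
}

# threshold maximizing balanced accuracy on (scores, labels); candidates are
# midpoints of adjacent distinct scores; ties broken toward the smallest
tune_threshold <- function(scores, y) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(cand, min(s) - 1e-9, max(s) + 1e-9)
  ba <- vapply(cand, function(th) {
    pred <- as.integer(scores > th)
    sens <- if (any(y == 1L)) mean(pred[y == 1L] == 1L) else NA_real_
    spec <- if (any(y == 0L)) mean(pred[y == 0L] == 0L) else NA_real_
    (sens + spec) / 2
  }, 0)
  cand[which.max(ba)]
}

#' Score frames with a fitted case model
#'
#' A tree's score for a frame is the (weighted) effusion fraction of the
#' leaf the frame reaches; a forest's score is the mean over its trees.
#' Comparing the score against the model's stored `threshold` yields the
#' class prediction.
#'
#' @param model a `case_model` from [fit_case()].
#' @param table feature table containing the model's feature columns.
#' @param per_tree return the n x n_trees matrix of per-tree scores instead
#'   of their mean (default FALSE).
#' @return Numeric vector of scores in \[0, 1\] (or a matrix if `per_tree`).
#' @export
predict_scores <- function(model, table, per_tree = FALSE) {
  stopifnot(inherits(model, "case_model"))
  cols <- model$features
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("feature-set mismatch; table lacks: ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(table[, cols, drop = FALSE])
  scores <- vapply(model$trees, function(tr) .predict_tree_cpp(tr, X),
                   numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  if (per_tree) scores else rowMeans(scores)
}

#' @rdname predict_scores
#' @export
predict_labels <- function(model, table) {
  ifelse(predict_scores(model, table) > model$threshold,
         "effusion", "no_effusion")
}

#' Confusion-matrix metrics
#'
#' Sensitivity is the effusion (positive-class) recall `TP / (TP + FN)`,
#' specificity the no-effusion recall `TN / (TN + FP)`; balanced accuracy is
#' their mean. A class missing from the truth is an error, not a silent 0/0.
#'
#' @param pred,truth character vectors of `"effusion"` / `"no_effusion"`.
#' @return Named numeric vector `(accuracy, sensitivity, specificity,
#'   balanced_accuracy)`.
#' @export
confusion_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) > 0L)
  if (!any(truth == "effusion") || !any(truth == "no_effusion"))
    stop("truth must contain both classes")
  pos <- truth == "effusion"
  sens <- mean(pred[pos] == "effusion")
  spec <- mean(pred[!pos] == "no_effusion")
  c(accuracy = mean(pred == truth), sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

#' ROC curve and AUC
#'
#' The ROC is traced by sweeping every distinct score as a threshold
#' (prediction positive when score > threshold); the AUC is the trapezoid
#' area, which gives tied scores half weight — identical to the
#' Mann-Whitney statistic `P(s+ > s-) + P(s+ = s-)/2`.
#'
#' @param scores numeric scores, larger meaning more effusion-like.
#' @param truth character labels; both classes must be present.
#' @return `list(roc = data.frame(fpr, tpr), auc = numeric)`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == "effusion"
  if (!any(pos) || all(pos)) stop("truth must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  distinct <- c(diff(s) != 0, TRUE)   # last row of each tie block
  tp <- cumsum(p)[distinct]; fp <- cumsum(!p)[distinct]
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classification case by repeated hold-out validation
#'
#' For every split: fit on the training side, score the test side, compute
#' confusion metrics at the model's threshold, and the ROC/AUC from the raw
#' scores. Per-iteration rows and across-iteration means are reported,
#' together with per-class mean-intensity summaries (for violin-style
#' inspection of the class separation).
#'
#' @param table feature table.
#' @param case a [case_spec()].
#' @param spec a [split_spec()].
#' @return An `evaluation_report`: `case_id`, `iterations` (data.frame),
#'   `means`, `rocs` (per-iteration ROC data.frames), and
#'   `intensity_summary`.
#' @export
evaluate_case <- function(table, case, spec = split_spec()) {
  splits <- make_splits(table, spec)
  iter_rows <- vector("list", length(splits))
  rocs <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    model <- fit_case(table[sp$train, , drop = FALSE], case,
                      seed = derive_seed(spec$seed, i, salt = 5L))
    test <- table[sp$test, , drop = FALSE]
    scores <- predict_scores(model, test)
    pred <- ifelse(scores > model$threshold, "effusion", "no_effusion")
    cm <- confusion_metrics(pred, test$label)
    ra <- roc_auc(scores, test$label)
    iter_rows[[i]] <- data.frame(iteration = i, t(cm), auc = ra$auc)
    rocs[[i]] <- ra$roc
  }
  iterations <- do.call(rbind, iter_rows)
  means <- colMeans(iterations[, -1, drop = FALSE])
  intensity_summary <- stats::aggregate(
    mean_intensity ~ label, data = table,
    FUN = function(v) c(mean = mean(v), sd = sd(v), median = median(v)))
  structure(list(case_id = case$case_id, case = case, spec = spec,
                 iterations = iterations, means = means, rocs = rocs,
                 intensity_summary = intensity_summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Case %d (%s, %s) over %d hold-out iterations:\n",
              x$case_id, x$case$input_set, x$case$model,
              nrow(x$iterations)))
  m <- x$means
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | balanced %.3f | AUC %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["balanced_accuracy"], m["auc"]))
  invisible(x)
}

#' Evaluate all three cases
#'
#' @param table feature table with the full 11-statistic set.
#' @param spec a [split_spec()].
#' @param cases list of [case_spec()]s (default Cases 1-3).
#' @return Named list of `evaluation_report`s (`case1`, `case2`, `case3`).
#' @export
evaluate_all_cases <- function(table, spec = split_spec(),
                               cases = lapply(1:3, case_spec)) {
  reports <- lapply(cases, function(cs) evaluate_case(table, cs, spec))
  names(reports) <- paste0("case", vapply(cases, `[[`, 0L, "case_id"))
  reports
}
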