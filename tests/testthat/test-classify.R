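# Feature tables built directly (no image rendering) keep these tests fast.

sim_table <- function(n = 100, n_eff = 35, seed = 1, sep = 4000) {
  set.seed(seed)
  lab <- c(rep("effusion", n_eff), rep("no_effusion", n - n_eff))
  base <- ifelse(lab == "effusion", 5000, 5000 + sep)
  tab <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    ear_id = sprintf("E%03d", seq_len(n)),
                    frame_index = 0L, label = lab)
  tab$mean_intensity <- base + rnorm(n, 0, 800)
  for (f in setdiff(swirotome:::FEATURE_NAMES, "mean_intensity"))
    tab[[f]] <- runif(n, 0, 1000)
  attr(tab, "input_set") <- "set2"
  tab
}

test_that("stratified frame-level splits hit the documented counts", {
  tab <- sim_table()
  spec <- split_spec(grouping = "frame", seed = 5)
  splits <- make_splits(tab, spec)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$train, 62)
    expect_length(sp$test, 38)
    expect_equal(sum(tab$label[sp$train] == "effusion"), 22)
    expect_equal(sum(tab$label[sp$test] == "effusion"), 13)
    expect_setequal(c(sp$train, sp$test), seq_len(100))
  }
  expect_identical(make_splits(tab, spec), splits)
})

test_that("ear grouping never splits an ear", {
  tab <- cohort_features(tiny_config(n_ears = 10, seed = 2))
  splits <- make_splits(tab, split_spec(grouping = "ear", seed = 3))
  for (sp in splits)
    expect_length(intersect(unique(tab$ear_id[sp$train]),
                            unique(tab$ear_id[sp$test])), 0)
  one_class <- tab[tab$label == "effusion", ]
  expect_error(make_splits(one_class, split_spec()), "both classes")
})

test_that("stratification keeps class fractions within one frame per class", {
  for (seed in 1:5) {
    tab <- sim_table(n = 137, n_eff = 48, seed = seed)
    splits <- make_splits(tab, split_spec(grouping = "frame", seed = seed))
    overall <- mean(tab$label == "effusion")
    for (sp in splits) {
      for (side in sp) {
        got <- sum(tab$label[side] == "effusion")
        expect_lte(abs(got - overall * length(side)), 1)
      }
    }
  }
})

test_that("Case 1 stump separates a separable table", {
  tab <- sim_table(n = 80, n_eff = 40, sep = 8000, seed = 2)
  tab$mean_intensity <- ifelse(tab$label == "effusion",
                               1000 + runif(80, -50, 50),
                               9000 + runif(80, -50, 50))
  model <- fit_case(tab, case_spec(1), seed = 1)
  pred <- predict_labels(model, tab)
  expect_identical(pred, tab$label)
  thr <- model$trees[[1]]$threshold[1]
  expect_gt(thr, 1050); expect_lt(thr, 8950)
  expect_error(fit_case(tab[tab$label == "effusion", ], case_spec(1)),
               "single-class")
})

test_that("set2 rescues a label carried only by the IQR feature", {
  set.seed(9)
  n <- 400
  lab <- rep(c("effusion", "no_effusion"), each = n / 2)
  tab <- data.frame(patient_id = "P", ear_id = sprintf("E%03d", 1:n),
                    frame_index = 0L, label = lab)
  for (f in swirotome:::FEATURE_NAMES) tab[[f]] <- runif(n, 0, 1000)
  tab$iqr <- ifelse(lab == "effusion", rnorm(n, 600, 40), rnorm(n, 300, 40))
  spec <- split_spec(grouping = "frame", seed = 4)
  ba2 <- evaluate_case(tab, case_spec(2), spec)$means["balanced_accuracy"]
  ba1 <- evaluate_case(tab, case_spec(1), spec)$means["balanced_accuracy"]
  expect_gte(ba2, 0.9)
  expect_lte(ba1, 0.6)
})

test_that("scores are leaf fractions and forests average them", {
  tab <- sim_table(n = 60, n_eff = 30, sep = 8000, seed = 3)
  model <- fit_case(tab, case_spec(1), seed = 1)
  sc <- predict_scores(model, tab)
  expect_true(all(sc %in% c(0, 1)))  # pure leaves on a separable table

  f3 <- fit_case(tab, case_spec(3, n_trees = 25), seed = 7)
  per_tree <- predict_scores(f3, tab, per_tree = TRUE)
  expect_equal(dim(per_tree), c(60, 25))
  expect_equal(rowMeans(per_tree), predict_scores(f3, tab))

  f3b <- fit_case(tab, case_spec(3, n_trees = 25), seed = 7)
  expect_identical(predict_scores(f3b, tab), predict_scores(f3, tab))
  expect_error(predict_scores(f3, tab[, 1:5]), "mismatch")
})

test_that("confusion metrics match hand values and the loop oracle", {
  cm <- confusion_metrics(c("effusion", "no_effusion", "no_effusion", "no_effusion"),
                          c("effusion", "effusion", "no_effusion", "no_effusion"))
  expect_equal(cm, c(accuracy = 0.75, sensitivity = 0.5, specificity = 1,
                     balanced_accuracy = 0.75))
  y <- c("effusion", "no_effusion")
  expect_equal(unname(confusion_metrics(y, y)), rep(1, 4))
  expect_error(confusion_metrics(y, c("effusion", "effusion")), "both classes")

  set.seed(12)
  labs <- c("effusion", "no_effusion")
  for (i in 1:500) {
    n <- sample(2:40, 1)
    truth <- c("effusion", "no_effusion", sample(labs, n, replace = TRUE))
    pred <- sample(labs, n + 2, replace = TRUE)
    expect_equal(confusion_metrics(pred, truth), oracle_confusion(pred, truth))
  }
})

test_that("trapezoid AUC equals the Mann-Whitney pairwise statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("effusion", "effusion", "no_effusion", "no_effusion"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("effusion", "no_effusion"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("effusion", 3)), "both classes")

  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    truth <- c("effusion", "no_effusion",
               sample(c("effusion", "no_effusion"), n, replace = TRUE))
    scores <- sample(round(runif(n + 2, 0, 1), sample(1:3, 1)))
    ra <- roc_auc(scores, truth)
    expect_equal(ra$auc, oracle_auc(scores, truth), tolerance = 1e-12)
    expect_true(all(diff(ra$roc$fpr) >= 0))
    expect_true(all(diff(ra$roc$tpr) >= 0))
    expect_equal(ra$roc[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(ra$roc[nrow(ra$roc), ], use.names = FALSE), c(1, 1))
  }
})

test_that("a one-iteration report equals the hand-composed chain", {
  tab <- sim_table(n = 90, n_eff = 30, seed = 6, sep = 2500)
  spec <- split_spec(n_iterations = 1, grouping = "frame", seed = 10)
  rep1 <- evaluate_case(tab, case_spec(3, n_trees = 40), spec)

  sp <- make_splits(tab, spec)[[1]]
  model <- fit_case(tab[sp$train, ], case_spec(3, n_trees = 40),
                    seed = swirotome:::derive_seed(spec$seed, 1, salt = 5L))
  scores <- predict_scores(model, tab[sp$test, ])
  pred <- ifelse(scores > model$threshold, "effusion", "no_effusion")
  cm <- confusion_metrics(pred, tab$label[sp$test])
  ra <- roc_auc(scores, tab$label[sp$test])
  expect_equal(unlist(rep1$iterations[1, -1]),
               c(cm, auc = ra$auc), tolerance = 1e-12)
  expect_equal(rep1$rocs[[1]], ra$roc)
})

test_that("reports are deterministic", {
  tab <- sim_table(n = 70, n_eff = 25, seed = 8, sep = 2000)
  spec <- split_spec(n_iterations = 3, grouping = "frame", seed = 2)
  r1 <- evaluate_case(tab, case_spec(3, n_trees = 30), spec)
  r2 <- evaluate_case(tab, case_spec(3, n_trees = 30), spec)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$means, r2$means)
})
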