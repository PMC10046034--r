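separable_data <- function(n_per_class = 40, gap = 5, p = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p, 0), n_per_class, p),
               matrix(rnorm(n_per_class * p, gap), n_per_class, p))
    list(X = X, y = factor(rep(c("normo", "hyper"), each = n_per_class),
                           levels = c("normo", "hyper")))
  })
}

test_that("accuracy is the percentage of correct labels", {
  expect_equal(accuracy(c(rep("a", 9), "b"), rep("a", 10)), 90)
  expect_equal(accuracy(rep("a", 7), rep("a", 7)), 100)
  expect_error(accuracy(character(0), character(0)), "non-empty")
  # brute-force count oracle on random label pairs
  withr::with_seed(11, {
    for (trial in 1:20) {
      n <- sample(5:50, 1)
      p <- sample(c("x", "y"), n, replace = TRUE)
      t <- sample(c("x", "y"), n, replace = TRUE)
      expect_equal(accuracy(p, t), 100 * sum(p == t) / n)
    }
  })
})

test_that("classifier spec validates family/kernel pairings", {
  expect_error(classifier_spec("svm", "cosine"), "not a legal")
  expect_error(classifier_spec("knn", "gaussian"), "not a legal")
  expect_error(classifier_spec("feedforward_nn", hidden = c(10)), "two")
  expect_equal(classifier_spec("ensemble")$kernel, "adaboost")
  expect_length(default_classifier_grid(), 15L)
})

test_that("every classifier family separates well-separated classes", {
  d <- separable_data()
  val <- validation_scheme("holdout", 0.25)
  for (clf in default_classifier_grid()) {
    res <- train_eval(d$X, d$y, clf, val, seed = 3)
    expect_gte(res$accuracy, 95)
  }
})

test_that("1-NN leave-one-out is perfect when every point is duplicated", {
  withr::with_seed(2, {
    base <- matrix(rnorm(20 * 3), 20, 3)
    X <- rbind(base, base)
    y <- factor(rep(rep(c("a", "b"), each = 10), 2))
  })
  res <- train_eval(X, y, classifier_spec("knn", "euclidean", k = 1),
                    validation_scheme("leave_one_out"))
  expect_equal(res$accuracy, 100)
  # LOO pooled accuracy equals the mean of the single-sample evaluations
  expect_equal(res$accuracy, mean(res$folds$accuracy))
  expect_equal(nrow(res$folds), nrow(X))
})

test_that("train_eval is reproducible and never trains on a one-class fold", {
  d <- separable_data(15, gap = 2)
  val <- validation_scheme("kfold", k = 5)
  r1 <- train_eval(d$X, d$y, classifier_spec("decision_tree"), val, seed = 5)
  r2 <- train_eval(d$X, d$y, classifier_spec("decision_tree"), val, seed = 5)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(r1$folds, r2$folds)
  # highly imbalanced labels force at least one refold attempt sometimes,
  # but training folds always end up with both classes
  y_imb <- factor(c(rep("a", 27), rep("b", 3)))
  r3 <- train_eval(d$X, y_imb, classifier_spec("decision_tree"),
                   validation_scheme("kfold", k = 3), seed = 1)
  expect_true(is.finite(r3$accuracy))
})

test_that("label permutation drives accuracy to chance", {
  d <- separable_data(60, gap = 5)
  accs <- vapply(1:25, function(s) {
    yp <- withr::with_seed(s, sample(d$y))
    train_eval(d$X, yp, classifier_spec("svm", "gaussian"),
               validation_scheme("holdout", 0.25), seed = s * 7)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 6)
})

test_that("run_experiment sweeps the grid and enforces cohort limits", {
  coh <- make_exact_cohort(30, 30)
  spec <- experiment_spec("map",
                          classifiers = list(classifier_spec("decision_tree")),
                          validations = list(validation_scheme("holdout", 0.2)),
                          seed = 4)
  res <- run_experiment(spec, coh)
  expect_equal(nrow(res), 1L)
  expect_identical(tidy(res), tidy(run_experiment(spec, coh)))  # deterministic
  expect_error(run_experiment(
    experiment_spec("map", n_original = 1000,
                    classifiers = list(classifier_spec("decision_tree"))),
    coh), "provides")
})

test_that("paper-mode balancing reports the enlarged subject count", {
  coh <- make_exact_cohort(68, 48)
  spec <- experiment_spec("systolic", balance = "smote", leakage_safe = FALSE,
                          classifiers = list(classifier_spec("knn", "euclidean")),
                          validations = list(validation_scheme("holdout", 0.2)),
                          seed = 8)
  res <- run_experiment(spec, coh)
  expect_true(all(res$n_subjects == 136))
  g <- glance(res)
  expect_equal(g$n_subjects, 136)
  expect_equal(g$labeling_rule, "systolic")
})

test_that("compare_rules extracts the best row per rule and flags ties", {
  coh <- make_exact_cohort(25, 25)
  mk <- function(rule) run_experiment(
    experiment_spec(rule,
                    classifiers = default_classifier_grid(compact = TRUE)[1:2],
                    validations = list(validation_scheme("holdout", 0.25)),
                    seed = 6), coh)
  runs <- list(systolic = mk("systolic"), diastolic = mk("diastolic"),
               map = mk("map"))
  cmp <- compare_rules(runs)
  expect_setequal(unique(cmp$rule), c("systolic", "diastolic", "map"))
  expect_true(all(!is.na(cmp$accuracy)))
  # a constructed tie is reported twice and flagged
  fake <- tibble::tibble(classifier = c("svm", "knn"), kernel = c("linear", "euclidean"),
                         validation = "10 fold", accuracy = c(80, 80))
  tied <- compare_rules(list(map = fake))
  expect_equal(nrow(tied), 2L)
  expect_true(all(tied$tied))
})

test_that("tidiers and autoplot return well-formed objects", {
  coh <- make_exact_cohort(25, 25)
  res <- run_experiment(
    experiment_spec("map", classifiers = default_classifier_grid(compact = TRUE),
                    validations = list(validation_scheme("holdout", 0.25)),
                    seed = 2), coh)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "experiment_result"))
  expect_s3_class(autoplot(res), "ggplot")
  rad <- extract_radii(make_cylinder(3, 20))
  expect_s3_class(autoplot(rad), "ggplot")
  expect_equal(nrow(tidy(rad)), 11L)
})

test_that("volumes round-trip through NIfTI and cohorts through CSV", {
  vol <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- read_volume_nifti(path)
  expect_equal(back, vol, tolerance = 1e-6)

  coh <- make_exact_cohort(5, 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, csv)
  back2 <- read_cohort_csv(csv)
  expect_equal(nrow(back2), nrow(coh))
  expect_s3_class(back2$label_map, "factor")
  expect_equal(as.character(back2$label_systolic),
               as.character(coh$label_systolic))
})
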