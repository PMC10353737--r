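two_clouds <- function(n = 30, sep = 8, seed = 71) {
  set.seed(seed)
  data.frame(group = factor(rep(c("healthy", "L5"), each = n),
                            levels = semg_classes()),
             f1 = c(rnorm(n), rnorm(n, sep)),
             f2 = c(rnorm(n), rnorm(n, sep)))
}

test_that("the forest separates separable clouds and is seed-deterministic", {
  d <- two_clouds()
  fit <- train_model(d, model_config(seed = 1))
  expect_identical(as.character(predict(fit, d)), as.character(d$group))

  probe <- two_clouds(seed = 99)
  fit2 <- train_model(d, model_config(seed = 1))
  expect_identical(predict(fit, probe, type = "prob"),
                   predict(fit2, probe, type = "prob"))

  single <- d[d$group == "L5", ]
  expect_error(train_model(single, model_config()), "degenerate")
})

test_that("stratified splits honor class counts and the training fraction", {
  labels <- factor(rep(c("L5", "S1", "healthy"), c(29, 29, 30)))
  sp <- stratified_holdout_split(labels, 0.5, seed = 3)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  counts <- table(labels[sp$train])
  expect_true(all(counts[c("L5", "S1")] %in% 14:15))
  expect_identical(as.integer(counts["healthy"]), 15L)

  small <- factor(rep(c("a", "b"), each = 4))
  sp2 <- stratified_holdout_split(small, 0.5, seed = 1)
  expect_identical(as.vector(table(small[sp2$train])), c(2L, 2L))

  sp3 <- stratified_holdout_split(labels, 0.5, seed = 4)
  expect_false(identical(sp$train, sp3$train))
  expect_identical(table(labels[sp$train]), table(labels[sp3$train]))
  expect_error(stratified_holdout_split(factor(c("a", "b", "b"))), "stratify")
})

test_that("metrics agree with hand computations and degenerate cases", {
  truth <- factor(rep(semg_classes(), each = 10), levels = semg_classes())
  perfect_prob <- diag(3)[rep(1:3, each = 10), ]
  colnames(perfect_prob) <- semg_classes()
  ev <- evaluate_predictions(truth, truth, perfect_prob)
  expect_equal(ev$accuracy, 1); expect_equal(ev$kappa, 1)
  expect_equal(ev$auc_macro, 1); expect_equal(ev$f1_macro, 1)

  # [[10,0,0],[0,0,10],[0,10,0]]: accuracy 1/3, expected agreement 1/3
  pred <- factor(rep(c("healthy", "S1", "L5"), each = 10),
                 levels = semg_classes())
  ev2 <- evaluate_predictions(truth, pred)
  expect_equal(ev2$accuracy, 1 / 3)
  expect_equal(ev2$kappa, 0)

  flat <- matrix(1 / 3, 30, 3, dimnames = list(NULL, semg_classes()))
  ev3 <- evaluate_predictions(truth, truth, flat)
  expect_true(all(abs(ev3$auc_per_class - 0.5) < 1e-12))

  expect_warning(
    evaluate_predictions(factor(rep(c("healthy", "L5"), 5),
                                levels = semg_classes()),
                         factor(rep("healthy", 10), levels = semg_classes())),
    "absent")
})

test_that("metrics are invariant under a consistent relabeling", {
  set.seed(72)
  truth <- factor(sample(semg_classes(), 60, TRUE), levels = semg_classes())
  pred <- factor(sample(semg_classes(), 60, TRUE), levels = semg_classes())
  ev <- evaluate_predictions(truth, pred)
  perm <- c(healthy = "S1", L5 = "healthy", S1 = "L5")
  ev_p <- evaluate_predictions(factor(perm[as.character(truth)],
                                      levels = semg_classes()),
                               factor(perm[as.character(pred)],
                                      levels = semg_classes()))
  for (m in c("accuracy", "precision_macro", "recall_macro", "f1_macro",
              "kappa"))
    expect_equal(ev[[m]], ev_p[[m]], tolerance = 1e-12)
})

test_that("one-vs-rest AUC equals the pairwise-comparison oracle", {
  set.seed(73)
  truth <- factor(sample(semg_classes(), 40, TRUE), levels = semg_classes())
  prob <- matrix(runif(120), 40, 3)
  prob <- prob / rowSums(prob)
  colnames(prob) <- semg_classes()
  ev <- evaluate_predictions(truth, truth, prob)
  for (cl in semg_classes())
    expect_equal(as.numeric(ev$auc_per_class[cl]),
                 auc_pairs(prob[, cl], truth == cl), tolerance = 1e-12)
})

test_that("repeated hold-out aggregates correctly and reproducibly", {
  cohort <- sample_feature_cohort(seed = 74)
  cfg <- model_config(n_trees = 50, n_repeats = 5, seed = 74)
  rep1 <- repeated_holdout(cohort, cfg)
  expect_identical(nrow(rep1$per_repeat), 5L)
  test_size <- sum(c(30, 29, 29) - round(c(30, 29, 29) * 0.5))
  expect_equal(sum(rep1$confusion_counts), 5 * test_size)  # pooled over repeats
  expect_true(all(abs(rowSums(rep1$confusion_rowpct) - 100) < 1e-9))
  expect_equal(sum(rep1$importance$share), 1, tolerance = 1e-9)
  expect_true(all(rep1$per_repeat$accuracy >= 0 & rep1$per_repeat$accuracy <= 1))
  expect_true(all(abs(rep1$per_repeat$kappa) <= 1))

  rep2 <- repeated_holdout(cohort, cfg)
  expect_identical(rep1$aggregate, rep2$aggregate)
  expect_identical(rep1$confusion_counts, rep2$confusion_counts)
})

test_that("a signal-free cohort yields chance-level agreement", {
  set.seed(75)
  null <- data.frame(group = factor(rep(semg_classes(), c(30, 29, 29)),
                                    levels = semg_classes()),
                     noise = rnorm(88))
  rep <- repeated_holdout(null, model_config(n_repeats = 10, seed = 75))
  expect_lt(abs(rep$aggregate[["kappa"]]), 0.1)
})

test_that("final model importances are normalized shares led by TA timing", {
  cohort <- sample_feature_cohort(seed = 76)
  fin <- final_model(cohort, model_config(seed = 76))
  expect_equal(sum(fin$importance$share), 1, tolerance = 1e-9)
  expect_true(all(fin$importance$share >= 0))
  expect_identical(fin$importance$feature[1], "TA_RMSpeaktime_diff")
})

test_that("duplicated feature columns split their importance", {
  # An exact duplicate of the top feature must share its impurity credit:
  # neither copy matches the single-column share on its own, both carry a
  # substantial part of it, and nothing is lost overall.  (The summed share
  # of the pair inflates somewhat — duplicated informative columns win more
  # splits — so equality of the sum is not asserted.)
  cohort <- sample_feature_cohort(seed = 77)
  base <- final_model(cohort, model_config(n_trees = 500, seed = 77))$importance
  dup <- cohort
  dup$TA_RMSpeaktime_dup <- dup$TA_RMSpeaktime_diff
  imp <- final_model(dup, model_config(n_trees = 500, seed = 77))$importance
  pair <- imp$share[match(c("TA_RMSpeaktime_diff", "TA_RMSpeaktime_dup"),
                          imp$feature)]
  single <- base$share[base$feature == "TA_RMSpeaktime_diff"]
  expect_true(all(pair > 0.25 * single))
  expect_true(all(pair < single))
  expect_gte(sum(pair), 0.8 * single)
})
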