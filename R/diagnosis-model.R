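#' Configuration of the random-forest diagnostic model
#'
#' @param n_trees Number of trees (bootstrap sub-datasets), default 50.
#' @param train_fraction Fraction of each class allocated to the training
#'   set, default 0.5.
#' @param n_repeats Number of repeated hold-out splits, default 10.
#' @param seed Master seed; per-repeat split and training seeds are derived
#'   sub-streams.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_trees = 50, train_fraction = 0.5, n_repeats = 10,
                         seed = 1) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1,
            n_repeats >= 1, is.numeric(seed))
  structure(list(n_trees = n_trees, train_fraction = train_fraction,
                 n_repeats = n_repeats, seed = seed,
                 classes = semg_classes()),
            class = "model_config")
}

# importance() drops names for single-feature forests; keep them.
gini_importance <- function(forest) {
  m <- randomForest::importance(forest)[, "MeanDecreaseGini", drop = FALSE]
  setNames(as.numeric(m), rownames(m))
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  cols <- cols[vapply(features[cols], is.numeric, TRUE)]
  if (length(cols) < 1) stop("no numeric feature columns")
  features[, cols, drop = FALSE]
}

#' Train the random-forest classifier
#'
#' Random forest with `config$n_trees` trees, bootstrap resampling of the
#' training rows per tree, and default split parameters (sqrt(p) candidate
#' features per split, unlimited depth).  Training is seeded and leaves the
#' caller's RNG untouched.
#'
#' @param features `data.frame` with a `group` factor and numeric feature
#'   columns (normally the eight [diff_feature_names()]).
#' @param config A [model_config()].
#' @return An object of class `semg_rf` wrapping the forest; use
#'   [predict.semg_rf()] for class or probability predictions.
#' @export
train_model <- function(features, config = model_config()) {
  stopifnot(inherits(config, "model_config"), "group" %in% names(features))
  y <- droplevels(factor(features$group))
  if (nlevels(y) < 2)
    stop("degenerate training set: fewer than 2 classes present")
  x <- feature_matrix(features)
  forest <- with_seed(config$seed,
                      randomForest::randomForest(x = x, y = y,
                                                 ntree = config$n_trees))
  structure(list(forest = forest, config = config,
                 feature_names = names(x), classes = levels(y)),
            class = "semg_rf")
}

#' @export
print.semg_rf <- function(x, ...) {
  cat(sprintf("<semg_rf> %d trees, %d features, classes: %s\n",
              x$config$n_trees, length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict from a trained diagnostic model
#'
#' @param object A `semg_rf` from [train_model()] / [final_model()].
#' @param newdata Feature `data.frame`.
#' @param type `"response"` for class labels or `"prob"` for class
#'   probabilities (rows sum to 1).
#' @param ... Unused.
#' @return Factor of predicted classes, or a probability matrix.
#' @export
predict.semg_rf <- function(object, newdata, type = c("response", "prob"),
                            ...) {
  type <- match.arg(type)
  predict(object$forest, feature_matrix(newdata), type = type)
}

#' Impurity-based feature-importance shares
#'
#' Mean decrease in Gini impurity per feature, normalized to shares summing
#' to 1.
#'
#' @param model A `semg_rf`.
#' @return `data.frame` with `feature` and `share`, sorted decreasing.
#' @export
importance_shares <- function(model) {
  stopifnot(inherits(model, "semg_rf"))
  imp <- gini_importance(model$forest)
  share <- imp / sum(imp)
  out <- data.frame(feature = names(share), share = as.numeric(share),
                    stringsAsFactors = FALSE)
  out[order(-out$share), , drop = FALSE]
}

#' Stratified hold-out split
#'
#' Splits row indices per class as close to `train_fraction` as integer
#' counts allow (round-to-even on .5); train and test are disjoint and
#' exhaustive.  Stratification prevents a class from being starved in small
#' cohorts.
#'
#' @param labels Factor (or coercible) of class labels; every class needs
#'   at least 2 rows.
#' @param train_fraction Training fraction.
#' @param seed Optional seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_holdout_split <- function(labels, train_fraction = 0.5,
                                     seed = NULL) {
  labels <- droplevels(factor(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("cannot stratify: class ", names(counts)[which.min(counts)],
         " has fewer than 2 rows")
  with_seed(seed, {
    train <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(length(idx) * train_fraction))
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
}

# Cohen's kappa: chance-corrected agreement with expected agreement from
# marginal products.
cohens_kappa <- function(truth, predicted, levels = NULL) {
  levels <- levels %||% union(levels(factor(truth)), levels(factor(predicted)))
  cm <- table(factor(truth, levels), factor(predicted, levels))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

# One-vs-rest ROC AUC from class probabilities via the rank (Mann-Whitney U)
# formulation; ties get the average rank.
ovr_auc <- function(truth, probabilities) {
  classes <- colnames(probabilities)
  per <- vapply(classes, function(cl) {
    pos <- truth == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(probabilities[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 1)
  # micro: pool all (is-this-class, probability) binary decisions
  y <- as.vector(vapply(classes, function(cl) truth == cl,
                        logical(length(truth))))
  s <- as.vector(probabilities[, classes])
  r <- rank(s)
  n1 <- sum(y); n0 <- sum(!y)
  micro <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(per_class = per, macro = mean(per, na.rm = TRUE), micro = micro)
}

#' Evaluate predictions against the truth
#'
#' Accuracy; precision, recall and F1 macro-averaged over the three classes
#' (micro-averaged values alongside); Cohen's kappa; and one-vs-rest ROC AUC
#' from class probabilities (macro and micro).  A class absent from the
#' truth is excluded from the macro averages with a warning.
#'
#' @param truth Factor of true classes.
#' @param predicted Factor of predicted classes (same length).
#' @param probabilities Matrix of class probabilities (one column per class,
#'   rows sum to 1); optional — AUCs are `NA` without it.
#' @param levels Class levels (default [semg_classes()]).
#' @return List of metrics plus the confusion `table` (truth in rows).
#' @export
evaluate_predictions <- function(truth, predicted, probabilities = NULL,
                                 levels = semg_classes()) {
  stopifnot(length(truth) == length(predicted))
  truth <- factor(truth, levels); predicted <- factor(predicted, levels)
  if (!is.null(probabilities)) {
    stopifnot(nrow(probabilities) == length(truth),
              all(abs(rowSums(probabilities) - 1) < 1e-6))
  }
  cm <- table(truth, predicted)
  present <- levels[rowSums(cm) > 0]
  if (length(present) < length(levels))
    warning("class(es) absent from truth excluded from macro averages: ",
            paste(setdiff(levels, present), collapse = ", "))
  prec <- rec <- f1 <- setNames(numeric(length(present)), present)
  for (cl in present) {
    tp <- cm[cl, cl]
    prec[cl] <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec[cl] <- tp / sum(cm[cl, ])
    f1[cl] <- if (prec[cl] + rec[cl] > 0)
      2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl]) else 0
  }
  auc <- if (is.null(probabilities)) list(macro = NA_real_, micro = NA_real_,
                                          per_class = NULL)
         else ovr_auc(truth, probabilities)
  list(accuracy = sum(diag(cm)) / sum(cm),
       precision_macro = mean(prec), recall_macro = mean(rec),
       f1_macro = mean(f1),
       precision_micro = sum(diag(cm)) / sum(cm),
       recall_micro = sum(diag(cm)) / sum(cm),
       kappa = cohens_kappa(truth, predicted, levels),
       auc_macro = auc$macro, auc_micro = auc$micro,
       auc_per_class = auc$per_class,
       confusion = cm)
}

#' Repeated stratified hold-out validation
#'
#' Runs `config$n_repeats` independent stratified splits (derived seed
#' streams), trains a fresh forest on each training half, evaluates on the
#' held-out half, and aggregates: per-repeat metrics, their means, the
#' pooled confusion matrix (counts and row-normalized percent), and
#' feature-importance shares averaged over repeats.
#'
#' @param features Labeled feature `data.frame` (`group` + feature columns).
#' @param config A [model_config()].
#' @return An object of class `evaluation_report`: list with `per_repeat`
#'   (data.frame), `aggregate` (named means), `confusion_counts`,
#'   `confusion_rowpct`, `importance`, `config`.
#' @export
#' @examples
#' cohort <- sample_feature_cohort(seed = 1)
#' rep <- repeated_holdout(cohort, model_config(seed = 1))
#' rep$aggregate[c("accuracy", "kappa", "auc_macro")]
repeated_holdout <- function(features, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  levels <- semg_classes()
  pooled <- matrix(0, 3, 3, dimnames = list(truth = levels, predicted = levels))
  per <- list(); imp_acc <- NULL
  metric_names <- c("accuracy", "precision_macro", "recall_macro", "f1_macro",
                    "kappa", "auc_macro", "auc_micro")
  for (r in seq_len(config$n_repeats)) {
    res <- tryCatch({
      split <- stratified_holdout_split(features$group, config$train_fraction,
                                        seed = derive_seed(config$seed, r, 1L))
      fit <- train_model(features[split$train, , drop = FALSE],
                         model_config(config$n_trees, config$train_fraction,
                                      config$n_repeats,
                                      seed = derive_seed(config$seed, r, 2L)))
      test <- features[split$test, , drop = FALSE]
      prob <- predict(fit, test, type = "prob")
      pred <- predict(fit, test, type = "response")
      ev <- evaluate_predictions(test$group, pred, prob, levels = levels)
      list(ev = ev, fit = fit)
    }, error = function(e)
      stop("repeat ", r, ": ", conditionMessage(e), call. = FALSE))
    pooled <- pooled + unclass(res$ev$confusion)
    per[[r]] <- c(repeat_ = r, unlist(res$ev[metric_names]))
    imp <- gini_importance(res$fit$forest)
    imp_acc <- if (is.null(imp_acc)) imp else imp_acc + imp
  }
  per_repeat <- as.data.frame(do.call(rbind, per))
  names(per_repeat)[1] <- "repeat_"
  aggregate <- colMeans(per_repeat[metric_names])
  share <- imp_acc / sum(imp_acc)
  importance <- data.frame(feature = names(share), share = as.numeric(share),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$share), , drop = FALSE]
  rowpct <- sweep(pooled, 1, pmax(rowSums(pooled), 1), "/") * 100
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 confusion_counts = pooled, confusion_rowpct = rowpct,
                 importance = importance, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<evaluation_report> %d repeats, %d trees\n  mean accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n  mean kappa %.3f, macro AUC %.3f (micro %.3f)\n",
    x$config$n_repeats, x$config$n_trees, a["accuracy"], a["precision_macro"],
    a["recall_macro"], a["f1_macro"], a["kappa"], a["auc_macro"],
    a["auc_micro"]))
  cat("  top feature:", x$importance$feature[1],
      sprintf("(%.0f%%)\n", 100 * x$importance$share[1]))
  invisible(x)
}

#' Train the final diagnostic model on the full cohort
#'
#' After validation is deemed satisfactory, the model is retrained on all
#' rows; importances are reported as percentage shares.
#'
#' @inheritParams repeated_holdout
#' @return List with `model` (a `semg_rf`) and `importance`
#'   (data.frame with `feature`, `share`).
#' @export
final_model <- function(features, config = model_config()) {
  fit <- train_model(features,
                     model_config(config$n_trees, config$train_fraction,
                                  config$n_repeats,
                                  seed = derive_seed(config$seed, 0L, 3L)))
  list(model = fit, importance = importance_shares(fit))
}

#' One-vs-rest ROC curve points
#'
#' Sensitivity / 1-specificity pairs for each class against the rest, from
#' class probabilities, at every distinct threshold.
#'
#' @param truth Factor of true classes.
#' @param probabilities Probability matrix (columns = classes).
#' @return `data.frame` with `class`, `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, probabilities) {
  do.call(rbind, lapply(colnames(probabilities), function(cl) {
    y <- truth == cl
    s <- probabilities[, cl]
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    data.frame(class = cl, threshold = th,
               fpr = vapply(th, function(t) mean(s[!y] >= t), 1),
               tpr = vapply(th, function(t) mean(s[y] >= t), 1))
  }))
}
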