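#' Configuration of an end-to-end pipeline run
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; every stage derives its own sub-streams.
#' @param n_healthy,n_l5,n_s1 Cohort sizes per class (defaults are the
#'   study's 30/29/29).
#' @param tier `"feature"` (sample classifier-ready difference features
#'   directly) or `"raw"` (simulate raw four-channel recordings and run the
#'   extraction stage).
#' @param n_repeats,n_trees,train_fraction Validation settings (see
#'   [model_config()]).
#' @param n_cycles Gait cycles per simulated recording (raw tier).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_healthy = 30, n_l5 = 29,
                       n_s1 = 29, tier = c("feature", "raw"),
                       n_repeats = 10, n_trees = 50, train_fraction = 0.5,
                       n_cycles = 8) {
  tier <- match.arg(tier)
  stopifnot(n_healthy >= 0, n_l5 >= 0, n_s1 >= 0)
  structure(list(out_dir = out_dir, seed = seed,
                 n_per_class = c(healthy = n_healthy, L5 = n_l5, S1 = n_s1),
                 tier = tier, n_repeats = n_repeats, n_trees = n_trees,
                 train_fraction = train_fraction, n_cycles = n_cycles),
            class = "run_config")
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[semgait] %s (%.2f s) %s", stage,
                  as.numeric(Sys.time()) - t0, paste0(...)))
}

write_manifest <- function(dir, stage, files, extra = list()) {
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(c(list(stage = stage, files = files), extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulation stage
#'
#' Feature tier: samples the labeled cohort and writes `cohort.csv`.  Raw
#' tier: simulates one four-channel recording per subject (symptomatic side
#' drawn at random for patients) and writes the per-subject CSV/JSON
#' triplets.  A manifest records every file, the seeds, and which reference
#' summaries calibrated the generator.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the written paths.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir <- file.path(config$out_dir, "sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (config$tier == "feature") {
    cohort <- sample_feature_cohort(config$n_per_class,
                                    seed = derive_seed(config$seed, 1L, 10L))
    path <- file.path(dir, "cohort.csv")
    write_feature_cohort(cohort, path)
    write_manifest(dir, "simulate", basename(path),
                   list(tier = "feature", seed = config$seed,
                        n_per_class = as.list(config$n_per_class),
                        calibration = "class-conditional log-normal laws fitted to the published bilateral-difference medians/IQRs"))
    stage_log("simulate", t0, nrow(cohort), " feature rows -> ", path)
    return(invisible(list(cohort = path)))
  }
  files <- character(); i <- 0
  for (cl in semg_classes()) {
    for (k in seq_len(config$n_per_class[[cl]])) {
      i <- i + 1
      sseed <- derive_seed(config$seed, i, 11L)
      side <- if (cl == "healthy") "none"
              else with_seed(derive_seed(config$seed, i, 12L),
                             sample(c("left", "right"), 1))
      prof <- default_subject_profile(cl, symptomatic_side = side,
                                      n_cycles = config$n_cycles)
      id <- sprintf("%s_%02d", cl, k)
      rec <- simulate_subject(prof, seed = sseed, id = id)
      files <- c(files, basename(write_recording(rec, dir, id, seed = sseed)))
    }
  }
  write_manifest(dir, "simulate", files,
                 list(tier = "raw", seed = config$seed,
                      n_per_class = as.list(config$n_per_class),
                      calibration = "burst timing/amplitude and spectrum corners calibrated to the published per-side cohort medians"))
  stage_log("simulate", t0, i, " recordings -> ", dir)
  invisible(list(dir = dir, files = files))
}

#' Extraction stage (raw tier)
#'
#' Reads every simulated recording, extracts per-side features and the
#' bilateral-difference vectors.  Subjects failing extraction are listed in
#' `exclusions.csv` with the reason, not silently dropped; the returned
#' status is 0 (all extracted) or 2 (partial).
#'
#' @param config A [run_config()] whose simulate stage has run in raw tier.
#' @return List with `features` (diff cohort data.frame), `per_side`
#'   (per-side feature data.frame), `exclusions` (data.frame) and `status`.
#' @export
pipeline_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir <- file.path(config$out_dir, "sim")
  metas <- list.files(dir, pattern = "_meta\\.json$")
  if (!length(metas)) stop("no raw recordings in ", dir,
                           " — run pipeline_simulate(tier = \"raw\") first")
  ids <- sub("_meta\\.json$", "", metas)
  diffs <- list(); sides <- list(); excl <- list()
  for (id in ids) {
    res <- tryCatch({
      rec <- read_recording(dir, id)
      sr <- extract_subject(rec)
      list(diff = bilateral_difference(sr),
           side = cbind(subject_id = id, group = rec$group,
                        symptomatic_side = rec$symptomatic_side,
                        sr$features))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) excl[[id]] <- data.frame(subject_id = id,
                                                    reason = res)
    else { diffs[[id]] <- res$diff; sides[[id]] <- res$side }
  }
  out <- file.path(config$out_dir, "features")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!length(diffs))
    stop("extraction failed for every subject; see reasons: ",
         paste(vapply(excl, `[[`, "", "reason"), collapse = "; "))
  features <- do.call(rbind, c(diffs, make.row.names = FALSE))
  features$group <- factor(features$group, semg_classes())
  per_side <- do.call(rbind, c(sides, make.row.names = FALSE))
  write_feature_cohort(features, file.path(out, "cohort.csv"))
  write.csv(per_side, file.path(out, "per_side.csv"), row.names = FALSE)
  exclusions <- if (length(excl))
    do.call(rbind, c(excl, make.row.names = FALSE))
  else data.frame(subject_id = character(), reason = character())
  write.csv(exclusions, file.path(out, "exclusions.csv"), row.names = FALSE)
  status <- if (length(excl)) 2L else 0L
  write_manifest(out, "extract",
                 c("cohort.csv", "per_side.csv", "exclusions.csv"),
                 list(status = status, n_extracted = length(diffs),
                      n_excluded = length(excl)))
  stage_log("extract", t0, length(diffs), " subjects extracted, ",
            length(excl), " excluded")
  invisible(list(features = features, per_side = per_side,
                 exclusions = exclusions, status = status))
}

pipeline_cohort_path <- function(config) {
  for (p in file.path(config$out_dir, c("features", "sim"), "cohort.csv"))
    if (file.exists(p)) return(p)
  stop("no cohort.csv under ", config$out_dir,
       " — run the simulate (and, for raw tier, extract) stage first")
}

#' Statistics stage
#'
#' Group summaries and three-group comparisons over the eight difference
#' features, written as CSV and JSON.
#'
#' @param config A [run_config()].
#' @return Invisibly, the comparison table ([diff_group_table()]).
#' @export
pipeline_stats <- function(config) {
  t0 <- as.numeric(Sys.time())
  cohort <- read_feature_cohort(pipeline_cohort_path(config))
  tab <- diff_group_table(cohort)
  out <- file.path(config$out_dir, "stats")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, file.path(out, "group_stats.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(out, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out, "stats", c("group_stats.csv", "group_stats.json"))
  stage_log("stats", t0, sum(tab$p_value < 0.05), "/", nrow(tab),
            " features significant")
  invisible(tab)
}

#' Training / validation stage
#'
#' Repeated stratified hold-out validation plus the final full-cohort model,
#' written as JSON and CSV artifacts (per-repeat metrics, pooled confusion
#' matrix in counts and row percent, per-class ROC points from the pooled
#' held-out probabilities, importance shares).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `evaluation_report` and the final
#'   model's importance table.
#' @export
pipeline_train <- function(config) {
  t0 <- as.numeric(Sys.time())
  cohort <- read_feature_cohort(pipeline_cohort_path(config))
  mc <- model_config(config$n_trees, config$train_fraction, config$n_repeats,
                     seed = derive_seed(config$seed, 2L, 20L))
  report <- repeated_holdout(cohort, mc)
  fin <- final_model(cohort, mc)
  # pooled held-out probabilities for the ROC artifact
  probs <- list(); truths <- list()
  for (r in seq_len(mc$n_repeats)) {
    split <- stratified_holdout_split(cohort$group, mc$train_fraction,
                                      seed = derive_seed(mc$seed, r, 1L))
    fit <- train_model(cohort[split$train, ],
                       model_config(mc$n_trees, mc$train_fraction,
                                    mc$n_repeats,
                                    seed = derive_seed(mc$seed, r, 2L)))
    probs[[r]] <- predict(fit, cohort[split$test, ], type = "prob")
    truths[[r]] <- cohort$group[split$test]
  }
  roc <- roc_points(unlist(lapply(truths, as.character)),
                    do.call(rbind, probs))
  out <- file.path(config$out_dir, "model")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_repeat, file.path(out, "per_repeat_metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$confusion_counts),
            file.path(out, "confusion_counts.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$confusion_rowpct),
            file.path(out, "confusion_rowpct.csv"), row.names = FALSE)
  write.csv(roc, file.path(out, "roc_points.csv"), row.names = FALSE)
  write.csv(fin$importance, file.path(out, "importance.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = as.list(report$aggregate),
         per_repeat = report$per_repeat,
         confusion_counts = unclass(report$confusion_counts),
         importance = fin$importance),
    file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", matrix = "rowmajor")
  write_manifest(out, "train",
                 c("per_repeat_metrics.csv", "confusion_counts.csv",
                   "confusion_rowpct.csv", "roc_points.csv", "importance.csv",
                   "evaluation.json"))
  stage_log("train", t0, sprintf("mean accuracy %.3f, kappa %.3f",
                                 report$aggregate["accuracy"],
                                 report$aggregate["kappa"]))
  invisible(list(report = report, importance = fin$importance))
}

#' Reporting stage
#'
#' Aggregates the headline numbers of a finished run into
#' `run_summary.json`: per-repeat and mean accuracies, kappa, macro AUC,
#' the importance ranking, and the significant difference features.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
pipeline_report <- function(config) {
  t0 <- as.numeric(Sys.time())
  ev <- jsonlite::read_json(file.path(config$out_dir, "model",
                                      "evaluation.json"),
                            simplifyVector = TRUE)
  st <- jsonlite::read_json(file.path(config$out_dir, "stats",
                                      "group_stats.json"),
                            simplifyVector = TRUE)
  summary <- list(
    seed = config$seed, tier = config$tier,
    n_per_class = as.list(config$n_per_class),
    n_repeats = config$n_repeats, n_trees = config$n_trees,
    per_repeat_accuracy = ev$per_repeat$accuracy,
    mean_accuracy = ev$aggregate$accuracy,
    mean_precision = ev$aggregate$precision_macro,
    mean_recall = ev$aggregate$recall_macro,
    mean_f1 = ev$aggregate$f1_macro,
    mean_kappa = ev$aggregate$kappa,
    mean_auc_macro = ev$aggregate$auc_macro,
    importance = ev$importance,
    significant_features = st$feature[st$p_value < 0.05])
  path <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  stage_log("report", t0, "-> ", path)
  invisible(summary)
}

#' Run the full pipeline
#'
#' simulate → (extract, raw tier only) → stats → train → report.  Any two
#' runs with an identical [run_config()] produce identical
#' `run_summary.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run summary list.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), seed = 1)
#' summary <- run_pipeline(cfg)
#' summary$mean_accuracy
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pipeline_simulate(config)
  if (config$tier == "raw") pipeline_extract(config)
  pipeline_stats(config)
  pipeline_train(config)
  pipeline_report(config)
}
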