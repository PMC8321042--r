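#' Configuration for the end-to-end cascade
#'
#' The four variants of the study design come from two switches: `branch`
#' (Stage 2A passes all background-filtered tiles forward; Stage 2B keeps
#' only tiles the cancer pre-filter classifies as cancer) and
#' `aggregation` (fixed majority vote over P1/P2/P3, or the trained
#' tabular learner on P1* and Fh). One global `seed` fans out
#' deterministically to per-stage seeds.
#'
#' @param tile_size tile side in pixels (default 512).
#' @param stride grid step; defaults to `tile_size` (non-overlapping).
#' @param gray_threshold Stage-1 background drop threshold (default 0.8).
#' @param branch `"all_tiles"` (2A) or `"cancer_subset"` (2B).
#' @param aggregation `"majority_vote"` or `"tabular"`.
#' @param her2_config a [her2_training_config()]; its seed is overridden
#'   by the fanned-out stage seed.
#' @param cancer_model optional trained cancer `tile_classifier` (or
#'   oracle function) for the 2B branch.
#' @param tabular_config a [tabular_learner_config()] for the tabular path.
#' @param seed global seed.
#' @param out_dir optional directory; when set, every intermediate
#'   artifact (tile manifest, probability CSV, feature CSV, predictions,
#'   run manifest) is written there.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(tile_size = 512L, stride = tile_size,
                            gray_threshold = 0.8,
                            branch = c("all_tiles", "cancer_subset"),
                            aggregation = c("majority_vote", "tabular"),
                            her2_config = her2_training_config(),
                            cancer_model = NULL,
                            tabular_config = tabular_learner_config(),
                            seed = 1L, out_dir = NULL) {
  structure(list(tile_size = as.integer(tile_size),
                 stride = as.integer(stride),
                 gray_threshold = gray_threshold,
                 branch = match.arg(branch),
                 aggregation = match.arg(aggregation),
                 her2_config = her2_config,
                 cancer_model = cancer_model,
                 tabular_config = tabular_config,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  # deterministic fan-out, kept within 32-bit integer range
  (seed * 131L + stage * 7919L) %% 2147483647L
}

#' Run the full cascade on train/test slide cohorts
#'
#' Stage 1 tiles and background-filters every slide; Stage 2 either passes
#' all tiles (branch `"all_tiles"`) or applies the cancer pre-filter
#' (`"cancer_subset"`); Stage 3 trains the HER2 tile classifier on the
#' weakly labelled training tiles and scores the test tiles; Stage 4
#' computes slide features; Stage 5 aggregates to slide calls, which are
#' evaluated against the test labels.
#'
#' @param train_slides,test_slides lists of `slide_image` objects with
#'   labels (training labels are required; test labels are used for
#'   evaluation only).
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage count messages.
#' @return list of class `pipeline_result`: `predictions` (data frame),
#'   `report` (an `evaluation_report`), `features_train`, `features_test`
#'   (feature tables), `manifest` (per-stage counts and config echo),
#'   `her2_model`, and `tabular_model` (when trained).
#' @export
run_her2_pipeline <- function(train_slides, test_slides, config = pipeline_config(),
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  slabels <- function(slides) {
    stats::setNames(vapply(slides, `[[`, integer(1), "label"),
                    vapply(slides, `[[`, character(1), "slide_id"))
  }
  train_labels <- slabels(train_slides)
  if (any(is.na(train_labels))) stop("every training slide needs a label")

  # Stage 1 (+ optional 2B) per cohort
  prep <- function(slides, cohort) {
    tiles <- unlist(lapply(slides, extract_tiles,
                           tile_size = config$tile_size,
                           stride = config$stride),
                    recursive = FALSE)
    kept <- filter_background(tiles, config$gray_threshold)
    say("[%s] stage 1: %d tiles extracted, %d kept after background filter",
        cohort, length(tiles), length(kept))
    if (config$branch == "cancer_subset") {
      if (is.null(config$cancer_model)) {
        stop("branch 'cancer_subset' requires a cancer_model in the config")
      }
      kept2 <- filter_cancer_tiles(config$cancer_model, kept, quiet = TRUE)
      say("[%s] stage 2B: %d tiles kept by cancer filter", cohort, length(kept2))
      kept2
    } else kept
  }
  tiles_train <- prep(train_slides, "train")
  tiles_test <- prep(test_slides, "test")
  if (length(tiles_train) == 0L) stop("no training tiles survived filtering")
  if (length(tiles_test) == 0L) stop("no test tiles survived filtering")

  # Stage 3
  hc <- config$her2_config
  hc$seed <- stage_seed(config$seed, 3L)
  labelled <- assign_slide_labels_to_tiles(tiles_train, as.list(train_labels))
  her2_model <- train_her2_classifier(labelled, hc)
  probs_train <- predict_slide_probabilities(her2_model, tiles_train)
  probs_test <- predict_slide_probabilities(her2_model, tiles_test)
  say("stage 3: classifier trained on %d tiles; scored %d train / %d test slides",
      length(tiles_train), length(probs_train), length(probs_test))

  # Stage 4
  features_train <- slide_feature_table(lapply(probs_train, compute_features))
  features_test <- slide_feature_table(lapply(probs_test, compute_features))

  # Stage 5
  tabular_model <- NULL
  if (config$aggregation == "majority_vote") {
    predictions <- aggregate_slides(features_test, "majority_vote")
  } else {
    tc <- config$tabular_config
    tc$seed <- stage_seed(config$seed, 5L)
    rows <- build_feature_matrix(features_train, labels = as.list(train_labels))
    tabular_model <- train_tabular_learner(rows, tc)
    predictions <- aggregate_slides(features_test, "tabular", model = tabular_model)
  }
  say("stage 5 (%s): %d slide calls", config$aggregation, nrow(predictions))

  test_labels <- slabels(test_slides)
  report <- NULL
  if (!any(is.na(test_labels))) {
    report <- evaluate_predictions(
      stats::setNames(predictions$call, predictions$slide_id), test_labels)
  }

  manifest <- list(
    config = list(tile_size = config$tile_size, stride = config$stride,
                  gray_threshold = config$gray_threshold,
                  branch = config$branch, aggregation = config$aggregation,
                  seed = config$seed),
    counts = list(train_tiles = length(tiles_train),
                  test_tiles = length(tiles_test),
                  train_slides = length(train_slides),
                  test_slides = length(test_slides)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(tile_manifest(tiles_test), file.path(od, "tile_manifest_test.csv"),
                     row.names = FALSE)
    write_slide_probabilities(probs_test, file.path(od, "probabilities_test.csv"))
    utils::write.csv(features_test, file.path(od, "features_test.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(od, "predictions.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(od, "run_manifest.yaml"))
  }

  structure(list(predictions = predictions, report = report,
                 features_train = features_train,
                 features_test = features_test,
                 manifest = manifest, her2_model = her2_model,
                 tabular_model = tabular_model),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$config$branch, "/",
      x$manifest$config$aggregation, "\n")
  cat("  tiles: train", x$manifest$counts$train_tiles,
      "| test", x$manifest$counts$test_tiles, "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Run the aggregation half of the cascade on probability bags
#'
#' Entry point for Stages 4-5 standalone: takes per-slide probability
#' vectors (e.g. from [generate_probability_bags()] or
#' [read_slide_probabilities()]) plus labels, splits train/test, and
#' produces slide calls by both aggregation strategies.
#'
#' @param bags list with elements carrying `p` (a `slide_probabilities`)
#'   and `label`, as returned by [generate_probability_bags()].
#' @param train_fraction fraction of bags used to train the tabular
#'   learner (stratified by label); majority vote needs no training but is
#'   evaluated on the same held-out set for comparability.
#' @param tabular_config a [tabular_learner_config()].
#' @param seed seed for the stratified split.
#' @return list with `vote_report`, `tabular_report` (both
#'   `evaluation_report`s on the held-out set), `predictions` (data frame
#'   with both calls), and `tabular_model`.
#' @export
run_bag_aggregation <- function(bags, train_fraction = 0.5,
                                tabular_config = tabular_learner_config(),
                                seed = 1L) {
  labels <- vapply(bags, `[[`, integer(1), "label")
  names(labels) <- vapply(bags, `[[`, character(1), "slide_id")
  features <- slide_feature_table(lapply(bags, function(b) compute_features(b$p)))

  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(bags), labels), function(ix) {
      sample(ix, round(train_fraction * length(ix)))
    }), use.names = FALSE)
  })
  idx_test <- setdiff(seq_along(bags), idx_train)
  ftr <- features[idx_train, ]; fte <- features[idx_test, ]

  rows <- build_feature_matrix(ftr, labels = as.list(labels[ftr$slide_id]))
  model <- train_tabular_learner(rows, tabular_config)

  vote <- aggregate_slides(fte, "majority_vote")
  tab <- aggregate_slides(fte, "tabular", model = model)
  truth <- labels[fte$slide_id]
  list(vote_report = evaluate_predictions(
         stats::setNames(vote$call, vote$slide_id), truth),
       tabular_report = evaluate_predictions(
         stats::setNames(tab$call, tab$slide_id), truth),
       predictions = data.frame(slide_id = fte$slide_id,
                                vote_call = vote$call,
                                tabular_call = tab$call,
                                tabular_probability = tab$probability,
                                truth = as.integer(truth)),
       tabular_model = model)
}
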