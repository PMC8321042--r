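# Stage 5: majority vote and the tabular learner.

test_that("majority vote equals the sum >= 2 rule on all 8 binary triples", {
  grid <- expand.grid(P1 = 0:1, P2 = 0:1, P3 = 0:1)
  got <- majority_vote(grid$P1, grid$P2, grid$P3)
  expect_identical(got, as.integer(rowSums(grid) >= 2))
  expect_identical(majority_vote(1, 1, 0), 1L)
  expect_identical(majority_vote(0, 0, 0), 0L)
  expect_error(majority_vote(1, 2, 0), "binary")
  expect_error(majority_vote(0.5, 0, 1), "binary")
})

feature_rows <- function(P1_star, labels = NULL, ids = NULL) {
  n <- length(P1_star)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  feats <- lapply(seq_len(n), function(i) {
    p <- rep(P1_star[i], 10)
    compute_features(p, slide_id = ids[i])
  })
  build_feature_matrix(feats, labels = labels)
}

test_that("the feature matrix carries exactly P1* and the five Fh columns", {
  labs <- stats::setNames(as.list(c(1L, 0L, 1L)), sprintf("s%02d", 1:3))
  rows <- feature_rows(c(0.9, 0.2, 0.8), labels = labs)
  expect_identical(names(rows),
                   c("slide_id", "P1_star", "F0.5", "F0.6", "F0.7", "F0.8",
                     "F0.9", "P"))
  expect_identical(nrow(rows), 3L)
  # inference mode: no label column
  rows_inf <- feature_rows(c(0.9, 0.2, 0.8))
  expect_false("P" %in% names(rows_inf))
  # optional binary indices behind the flag
  feats <- lapply(1:2, function(i) compute_features(rep(0.7, 5),
                                                    slide_id = paste0("x", i)))
  with_idx <- build_feature_matrix(feats, include_indices = TRUE)
  expect_true(all(c("P1", "P2", "P3") %in% names(with_idx)))
})

test_that("the feature matrix rejects duplicate slides and missing labels", {
  feats <- lapply(c("a", "a"), function(id) compute_features(rep(0.5, 4),
                                                             slide_id = id))
  expect_error(build_feature_matrix(feats), "duplicate")
  feats2 <- lapply(c("a", "b"), function(id) compute_features(rep(0.5, 4),
                                                              slide_id = id))
  expect_error(build_feature_matrix(feats2, labels = list(a = 1L)),
               "'b'")
})

test_that("the tabular learner reaches training accuracy 1 on separable rows", {
  P1s <- c(seq(0.7, 0.95, length.out = 10),
           seq(0.05, 0.3, length.out = 10))
  ids <- sprintf("s%02d", 1:20)
  labs <- stats::setNames(as.list(rep(c(1L, 0L), each = 10)), ids)
  rows <- feature_rows(P1s, labels = labs, ids = ids)
  m <- train_tabular_learner(rows, tabular_learner_config(epochs = 50L, seed = 1))
  pred <- predict(m, rows)
  expect_identical(pred$call, rows$P)
  expect_equal(utils::tail(m$accuracy_log, 1), 1)
})

test_that("degenerate capacity (1,1,1 hidden) still trains", {
  ids <- sprintf("s%02d", 1:8)
  labs <- stats::setNames(as.list(rep(c(1L, 0L), each = 4)), ids)
  rows <- feature_rows(c(0.9, 0.85, 0.8, 0.95, 0.1, 0.2, 0.15, 0.05),
                       labels = labs, ids = ids)
  m <- train_tabular_learner(rows, tabular_learner_config(
    hidden_layers = c(1L, 1L, 1L), epochs = 30L, seed = 2))
  expect_s3_class(m, "tabular_learner")
  expect_true(all(predict(m, rows)$probability >= 0 &
                    predict(m, rows)$probability <= 1))
})

test_that("tabular inference is deterministic and validates its columns", {
  ids <- sprintf("s%02d", 1:10)
  labs <- stats::setNames(as.list(rep(c(1L, 0L), 5)), ids)
  rows <- feature_rows(rep(c(0.9, 0.1), 5), labels = labs, ids = ids)
  m <- train_tabular_learner(rows, tabular_learner_config(epochs = 40L, seed = 3))
  p1 <- predict(m, rows[1, ]); p2 <- predict(m, rows[1, ])
  expect_identical(p1, p2)
  # extreme rows on a separable model
  lo <- feature_rows(0.02, ids = "lo"); hi <- feature_rows(0.98, ids = "hi")
  expect_identical(predict(m, lo)$call, 0L)
  expect_identical(predict(m, hi)$call, 1L)
  broken <- rows[, setdiff(names(rows), "F0.7")]
  expect_error(predict(m, broken), "F0.7")
})

test_that("training rejects unlabelled or single-class row sets", {
  rows_nolab <- feature_rows(c(0.9, 0.1))
  expect_error(train_tabular_learner(rows_nolab), "label column")
  ids <- c("a", "b")
  labs <- stats::setNames(as.list(c(1L, 1L)), ids)
  rows_one <- feature_rows(c(0.9, 0.8), labels = labs, ids = ids)
  expect_error(train_tabular_learner(rows_one), "single class")
})

test_that("both aggregation paths recover labels on well-separated bags", {
  bags <- generate_probability_bags(probability_bag_spec(
    200, tiles_per_slide = 50, high_component_mean = 0.8,
    low_component_mean = 0.2, positive_tile_rate_in_positive_slides = 0.6,
    seed = 42))
  res <- run_bag_aggregation(bags, seed = 7)
  expect_gte(res$vote_report$accuracy, 0.9)
  expect_gte(res$tabular_report$accuracy, 0.9)
  expect_identical(nrow(res$predictions),
                   res$vote_report$n)
})
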