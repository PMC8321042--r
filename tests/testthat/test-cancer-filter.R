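# Stage 2B: BACH label collapsing and the cancer-tile pre-filter.

test_that("label collapsing is total on the four BACH classes and rejects the rest", {
  expect_identical(collapse_bach_labels("normal"), "no cancer")
  expect_identical(collapse_bach_labels("benign"), "no cancer")
  expect_identical(collapse_bach_labels("in situ carcinoma"), "cancer")
  expect_identical(collapse_bach_labels("invasive carcinoma"), "cancer")
  expect_identical(
    collapse_bach_labels(c("benign", "invasive carcinoma", "normal")),
    c("no cancer", "cancer", "no cancer"))
  expect_error(collapse_bach_labels("Invasive"), "unknown BACH label")
  expect_error(collapse_bach_labels("tumour"), "unknown BACH label")
})

test_that("oracle models make the filter an identity or an annihilator", {
  tiles <- gray_tiles(c(0.2, 0.4, 0.6))
  keep_all <- function(ts) rep(1, length(ts))
  drop_all <- function(ts) rep(0, length(ts))
  expect_identical(filter_cancer_tiles(keep_all, tiles, quiet = TRUE), tiles,
                   ignore_attr = TRUE)
  expect_length(filter_cancer_tiles(drop_all, tiles, quiet = TRUE), 0L)
  expect_length(filter_cancer_tiles(keep_all, list(), quiet = TRUE), 0L)
})

test_that("a tie at exactly 0.5 is classified as cancer (kept)", {
  tiles <- gray_tiles(c(0.3, 0.3))
  half <- function(ts) c(0.5, 0.4999)
  kept <- filter_cancer_tiles(half, tiles, quiet = TRUE)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$slide_id, tiles[[1]]$slide_id)
})

test_that("the classifier recovers the planted cancer cue on held-out tiles", {
  sets <- cue_tile_sets()
  m <- train_cancer_classifier(
    c(sets$pos[1:150], sets$neg[1:150]),
    rep(c("cancer", "no cancer"), each = 150),
    tile_classifier_config(seed = 2))
  acc <- mean(c(predict(m, sets$pos[151:200]) >= 0.5,
                predict(m, sets$neg[151:200]) < 0.5))
  expect_gte(acc, 0.9)
})

test_that("the kept fraction tracks the planted cancer fraction", {
  sets <- cue_tile_sets()
  m <- train_cancer_classifier(
    c(sets$pos[1:150], sets$neg[1:150]),
    rep(c("cancer", "no cancer"), each = 150),
    tile_classifier_config(seed = 2))
  sl <- generate_synthetic_slide(synthetic_slide_spec(
    640, 640, tile_px = 64, tissue_fraction = 1,
    positive_tile_fraction = 0.3, slide_label = 1L, seed = 33))
  tiles <- extract_tiles(sl, 64)
  kept <- filter_cancer_tiles(m, tiles, quiet = TRUE)
  expect_lt(abs(length(kept) / length(tiles) - 0.3), 0.1)
})

test_that("duplicating the training set barely moves the decision function", {
  sets <- cue_tile_sets()
  tiles <- c(sets$pos[1:80], sets$neg[1:80])
  labs <- rep(c(1L, 0L), each = 80)
  cfg <- tile_classifier_config(seed = 5, augment_copies = 0L)
  m1 <- train_cancer_classifier(tiles, labs, cfg)
  m2 <- train_cancer_classifier(c(tiles, tiles), c(labs, labs), cfg)
  held <- c(sets$pos[81:120], sets$neg[81:120])
  p1 <- predict(m1, held); p2 <- predict(m2, held)
  expect_gte(mean((p1 >= 0.5) == (p2 >= 0.5)), 0.95)
})

test_that("degenerate configurations behave as documented", {
  tiles <- gray_tiles(c(0.2, 0.3, 0.6, 0.7))
  labs <- c(1L, 1L, 0L, 0L)
  # no training: prior model, pipeline still runs
  m0 <- train_cancer_classifier(tiles, labs,
                                tile_classifier_config(head_epochs = 0L,
                                                       full_epochs = 0L))
  expect_equal(predict(m0, tiles), rep(0.5, 4))
  expect_error(train_cancer_classifier(tiles, rep(1L, 4),
                                       tile_classifier_config()),
               "single class")
})

test_that("with an oracle model Stage 3 never sees a non-cancer tile", {
  cohort <- desk_cohort(6)
  oracle <- oracle_cue_model(cohort)
  tiles <- unlist(lapply(cohort, extract_tiles, tile_size = 64L),
                  recursive = FALSE)
  kept_bg <- filter_background(tiles)
  kept <- filter_cancer_tiles(oracle, kept_bg, quiet = TRUE)
  expect_true(all(tile_is_cue(kept, cohort)))
  # and exactly the planted set survives
  expect_identical(length(kept), sum(tile_is_cue(kept_bg, cohort)))
})
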