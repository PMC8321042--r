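# Synthetic-data module: planted ground truth for slides and probability bags.

test_that("identical spec and seed give a bit-identical slide", {
  spec <- synthetic_slide_spec(2048, 1536, tile_px = 512,
                               tissue_fraction = 0.5, seed = 7)
  a <- generate_synthetic_slide(spec)
  b <- generate_synthetic_slide(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
})

test_that("a no-tissue slide is entirely dropped by the background filter", {
  sl <- generate_synthetic_slide(synthetic_slide_spec(
    256, 192, tile_px = 64, tissue_fraction = 0, seed = 1))
  tiles <- extract_tiles(sl, 64)
  expect_true(all(vapply(tiles, `[[`, numeric(1), "mean_gray") > 0.8))
  expect_length(filter_background(tiles), 0L)
})

test_that("slides smaller than one tile are rejected with a clear message", {
  expect_error(synthetic_slide_spec(100, 600, tile_px = 512),
               "at least one tile")
})

test_that("the surviving-tile fraction tracks the requested tissue fraction", {
  sl <- generate_synthetic_slide(synthetic_slide_spec(
    512, 512, tile_px = 64, tissue_fraction = 0.5, seed = 3))
  tiles <- extract_tiles(sl, 64)
  surv <- length(filter_background(tiles)) / length(tiles)
  expect_lt(abs(surv - 0.5), 0.15)
})

test_that("the generator's mask and the Stage-1 filter agree on at least 85% of cells", {
  for (seed in c(2, 9, 17)) {
    sl <- generate_synthetic_slide(synthetic_slide_spec(
      512, 320, tile_px = 64, tissue_fraction = 0.6, seed = seed))
    tiles <- extract_tiles(sl, 64)
    kept <- vapply(tiles, `[[`, numeric(1), "mean_gray") <= 0.8
    m <- sl$mask[order(sl$mask$tile_row, sl$mask$tile_col), ]
    # extract_tiles is row-major too
    expect_gte(mean(kept == m$is_tissue), 0.85)
  }
})

test_that("bag labels honour the positive-slide fraction exactly in round cases", {
  bags <- generate_probability_bags(probability_bag_spec(
    10, positive_slide_fraction = 0.4, seed = 2))
  expect_identical(sum(vapply(bags, `[[`, integer(1), "label")), 4L)
})

test_that("bags are reproducible and probabilities stay in [0,1]", {
  spec <- probability_bag_spec(20, seed = 13)
  a <- generate_probability_bags(spec)
  b <- generate_probability_bags(spec)
  expect_identical(lapply(a, `[[`, "p"), lapply(b, `[[`, "p"))
  allp <- unlist(lapply(a, function(x) x$p$p))
  expect_true(all(allp >= 0 & allp <= 1))
})

test_that("a zero positive-tile rate leaves every slide with P1 = 0", {
  bags <- generate_probability_bags(probability_bag_spec(
    12, low_component_mean = 0.1,
    positive_tile_rate_in_positive_slides = 0, seed = 4))
  P1 <- vapply(bags, function(b) positivity_P1(b$p$p)$P1, integer(1))
  expect_true(all(P1 == 0L))
})

test_that("negative-slide probabilities centre on the low component mean", {
  spec <- probability_bag_spec(200, tiles_per_slide = 50,
                               low_component_mean = 0.2, seed = 11)
  bags <- generate_probability_bags(spec)
  neg <- unlist(lapply(Filter(function(b) b$label == 0L, bags),
                       function(b) b$p$p))
  # Beta(mean m, concentration k) variance = m(1-m)/(k+1)
  se <- sqrt(0.2 * 0.8 / (spec$concentration + 1) / length(neg))
  expect_lt(abs(mean(neg) - 0.2), 3 * se)
})

test_that("invalid bag specs are rejected", {
  expect_error(probability_bag_spec(10, tiles_per_slide = 0), "at least 1")
  expect_error(probability_bag_spec(10, high_component_mean = 0.4))
  expect_error(probability_bag_spec(10, low_component_mean = 0.7))
})

test_that("slide accuracy rises monotonically as the separability dial opens", {
  lows <- c(0.45, 0.35, 0.2); highs <- c(0.55, 0.65, 0.8)
  rates <- c(0.3, 0.45, 0.6)
  acc <- vapply(1:3, function(i) {
    bags <- generate_probability_bags(probability_bag_spec(
      150, low_component_mean = lows[i], high_component_mean = highs[i],
      positive_tile_rate_in_positive_slides = rates[i], seed = 21))
    run_bag_aggregation(bags, seed = 9)$vote_report$accuracy
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})

test_that("bags round-trip through the per-tile CSV contract", {
  bags <- generate_probability_bags(probability_bag_spec(6, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_probability_bags(bags, f)
  back <- read_slide_probabilities(f)
  expect_identical(names(back), vapply(bags, `[[`, character(1), "slide_id"))
  expect_equal(back[["bag_001"]]$p, bags[[1]]$p$p)
  unlink(f)
})
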