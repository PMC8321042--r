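# Shared fixtures, all generated in code. Heavyweight objects are memoised
# per test run so several test files can reuse one synthetic cohort.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a tile with constant pixel value (0..255) without touching internals
constant_tile <- function(value, size = 4L, slide_id = "t") {
  img <- list(slide_id = slide_id,
              pixels = array(value, c(size, size, 3)),
              width_px = size, height_px = size)
  extract_tiles(img, size)[[1]]
}

# a tile list with prescribed mean-gray values (constant gray tiles)
gray_tiles <- function(grays, size = 4L) {
  lapply(seq_along(grays), function(i) {
    constant_tile(grays[i] * 255, size, slide_id = sprintf("g%02d", i))
  })
}

# desk-scale cohort of labelled synthetic slides (64-px grid cells)
desk_cohort <- function(n = 20, seed = 5) {
  memo(sprintf("cohort_%d_%d", n, seed),
       generate_synthetic_cohort(n, seed = seed))
}

# tiles carrying / not carrying the planted positive cue, for classifier
# tests; built from all-tissue synthetic slides
cue_tile_sets <- function() {
  memo("cue_tiles", {
    mk <- function(pos, seed) {
      sl <- generate_synthetic_slide(synthetic_slide_spec(
        512, 512, tile_px = 64, tissue_fraction = 1,
        positive_tile_fraction = if (pos) 1 else 0,
        slide_label = as.integer(pos), seed = seed))
      extract_tiles(sl, 64)
    }
    list(pos = unlist(lapply(1:4, function(s) mk(TRUE, s)), recursive = FALSE),
         neg = unlist(lapply(5:8, function(s) mk(FALSE, s)), recursive = FALSE))
  })
}

# cohort where BOTH classes carry the cue (cancer occurs in HER2-negative
# slides too): positives at rate 0.7, negatives at 0.3 — needed for the
# cancer-subset branch, where an oracle pre-filter keeps only cue tiles
mixed_cue_cohort <- function(n = 12, seed = 40) {
  memo(sprintf("mixed_%d_%d", n, seed), {
    lapply(seq_len(n), function(i) {
      lab <- as.integer(i %% 2L == 1L)
      generate_synthetic_slide(synthetic_slide_spec(
        512, 320, tile_px = 64, tissue_fraction = 0.6,
        positive_tile_fraction = if (lab == 1L) 0.7 else 0.3,
        slide_label = lab, seed = seed * 1000L + i,
        slide_id = sprintf("mx_%03d", i)))
    })
  })
}

# ground-truth cue lookup for tiles of a cohort slide
tile_is_cue <- function(tiles, cohort) {
  sids <- vapply(cohort, `[[`, character(1), "slide_id")
  vapply(tiles, function(t) {
    s <- cohort[[match(t$slide_id, sids)]]
    r <- t$origin_y %/% s$tile_px; cc <- t$origin_x %/% s$tile_px
    s$mask$is_positive[s$mask$tile_row == r & s$mask$tile_col == cc]
  }, logical(1))
}

# oracle models built from synthetic ground truth
oracle_cue_model <- function(cohort) {
  function(tiles) as.numeric(tile_is_cue(tiles, cohort))
}

# rank-based AUC (Wilcoxon statistic)
simple_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
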