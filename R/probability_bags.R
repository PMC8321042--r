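#' Specification of synthetic tile-probability bags
#'
#' Describes bags of per-tile HER2 probabilities with planted slide labels,
#' emulating the output contract of the tile classifier so the feature and
#' aggregation stages can be exercised standalone. Probabilities are drawn
#' from two unimodal Beta components: a "low" component (mean below 0.5,
#' the appearance of HER2-negative tissue) and a "high" component (mean
#' above 0.5). A negative slide's bag uses only the low component; in a
#' positive slide each tile is independently assigned to the high
#' component with probability `positive_tile_rate_in_positive_slides`.
#'
#' @param n_slides number of slides (bags).
#' @param tiles_per_slide either a single count or a length-2 range from
#'   which each bag's size is drawn uniformly.
#' @param positive_slide_fraction fraction of slides labelled positive;
#'   the positive count is `round(fraction * n_slides)`.
#' @param high_component_mean mean of the high Beta component, in (0.5, 1).
#' @param low_component_mean mean of the low Beta component, in (0, 0.5).
#' @param positive_tile_rate_in_positive_slides per-tile probability of the
#'   high component within a positive slide, in (0, 1]; 0 is accepted and
#'   makes positive bags indistinguishable from negative ones.
#' @param concentration Beta concentration (a + b) of both components;
#'   larger values give tighter components.
#' @param seed integer seed; identical spec + seed gives identical bags.
#' @return an object of class `probability_bag_spec`.
#' @export
probability_bag_spec <- function(n_slides, tiles_per_slide = 50L,
                                 positive_slide_fraction = 0.5,
                                 high_component_mean = 0.8,
                                 low_component_mean = 0.2,
                                 positive_tile_rate_in_positive_slides = 0.6,
                                 concentration = 10,
                                 seed = 1L) {
  stopifnot(n_slides >= 1,
            positive_slide_fraction >= 0, positive_slide_fraction <= 1,
            high_component_mean > 0.5, high_component_mean < 1,
            low_component_mean > 0, low_component_mean < 0.5,
            positive_tile_rate_in_positive_slides >= 0,
            positive_tile_rate_in_positive_slides <= 1,
            concentration > 0)
  if (any(tiles_per_slide < 1)) stop("tiles_per_slide must be at least 1")
  if (!length(tiles_per_slide) %in% 1:2) {
    stop("tiles_per_slide must be a count or a length-2 range")
  }
  structure(list(n_slides = as.integer(n_slides),
                 tiles_per_slide = as.integer(tiles_per_slide),
                 positive_slide_fraction = positive_slide_fraction,
                 high_component_mean = high_component_mean,
                 low_component_mean = low_component_mean,
                 positive_tile_rate_in_positive_slides =
                   positive_tile_rate_in_positive_slides,
                 concentration = concentration,
                 seed = as.integer(seed)),
            class = "probability_bag_spec")
}

rbeta_mean <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

#' Generate synthetic probability bags with planted labels
#'
#' @param spec a [probability_bag_spec()].
#' @return a list with one element per slide, each a list with `slide_id`,
#'   `p` (a `slide_probabilities` object), `label` (0/1) and
#'   `tile_is_high` (logical ground-truth component membership per tile).
#' @examples
#' bags <- generate_probability_bags(probability_bag_spec(10,
#'   positive_slide_fraction = 0.4, seed = 2))
#' sum(vapply(bags, `[[`, integer(1), "label"))
#' @export
generate_probability_bags <- function(spec) {
  stopifnot(inherits(spec, "probability_bag_spec"))
  n_pos <- round(spec$positive_slide_fraction * spec$n_slides)
  labels <- c(rep(1L, n_pos), rep(0L, spec$n_slides - n_pos))
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_slides), function(j) {
      ts <- if (length(spec$tiles_per_slide) == 2L) {
        sample(spec$tiles_per_slide[1]:spec$tiles_per_slide[2], 1L)
      } else spec$tiles_per_slide
      is_high <- if (labels[j] == 1L) {
        stats::runif(ts) < spec$positive_tile_rate_in_positive_slides
      } else rep(FALSE, ts)
      p <- numeric(ts)
      p[is_high] <- rbeta_mean(sum(is_high), spec$high_component_mean,
                               spec$concentration)
      p[!is_high] <- rbeta_mean(sum(!is_high), spec$low_component_mean,
                                spec$concentration)
      sid <- sprintf("bag_%03d", j)
      list(slide_id = sid,
           p = slide_probabilities(sid, p,
                                   tile_keys = data.frame(origin_x = seq_len(ts) - 1L,
                                                          origin_y = 0L)),
           label = labels[j],
           tile_is_high = is_high)
    })
  })
}

#' Write probability bags to a per-tile CSV
#'
#' Columns: `slide_id`, `tile_row`, `tile_col`, `probability`,
#' `slide_label` — the interchange format between the imaging half of the
#' pipeline and the feature/aggregation half.
#'
#' @param bags output of [generate_probability_bags()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_probability_bags <- function(bags, path) {
  rows <- do.call(rbind, lapply(bags, function(b) {
    data.frame(slide_id = b$slide_id,
               tile_row = 0L,
               tile_col = seq_along(b$p$p) - 1L,
               probability = b$p$p,
               slide_label = b$label)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
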