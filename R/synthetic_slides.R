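#' Specification of a synthetic H&E-like slide
#'
#' Describes a synthetic whole-slide-scale image built on a regular tile
#' grid: bright near-white background cells, stained-tissue cells drawn in
#' an eosin-pink palette with haematoxylin-blue nuclear blobs, and an
#' optional "positive cue" (a hue shift towards purple plus a higher
#' nuclear-blob density) planted in a controllable fraction of tissue
#' cells. The cue is the learnable stand-in for tumour morphology that the
#' tile classifiers are asked to recover.
#'
#' @param width_px,height_px image dimensions in pixels; must each be at
#'   least `tile_px`.
#' @param tile_px side of the square grid cell (and of the tiles the
#'   Stage-1 tiler is expected to cut), in pixels.
#' @param background_brightness target mean gray of background cells on
#'   the 0..1 brightness scale (1 = white). Must sit above the Stage-1
#'   drop threshold for the generator's ground truth to be recoverable.
#' @param tissue_fraction fraction of grid cells carrying tissue, in [0,1].
#' @param positive_tile_fraction fraction of tissue cells carrying the
#'   positive visual cue. In the default presets this is only non-zero for
#'   slides with `slide_label = 1`.
#' @param slide_label binary HER2 status of the slide (0 or 1).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   image. No global random state is touched.
#' @param slide_id identifier recorded on the image and in manifests.
#' @return an object of class `synthetic_slide_spec`.
#' @seealso [generate_synthetic_slide()]
#' @export
synthetic_slide_spec <- function(width_px, height_px, tile_px = 512L,
                                 background_brightness = 0.95,
                                 tissue_fraction = 0.5,
                                 positive_tile_fraction = 0,
                                 slide_label = 0L,
                                 seed = 1L,
                                 slide_id = sprintf("synthetic_%d", seed)) {
  stopifnot(width_px >= 1, height_px >= 1, tile_px >= 1,
            background_brightness >= 0, background_brightness <= 1,
            tissue_fraction >= 0, tissue_fraction <= 1,
            positive_tile_fraction >= 0, positive_tile_fraction <= 1,
            slide_label %in% c(0L, 1L))
  if (width_px < tile_px || height_px < tile_px) {
    stop("slide dimensions (", width_px, "x", height_px,
         ") must be at least one tile (", tile_px, " px)")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 tile_px = as.integer(tile_px),
                 background_brightness = background_brightness,
                 tissue_fraction = tissue_fraction,
                 positive_tile_fraction = positive_tile_fraction,
                 slide_label = as.integer(slide_label),
                 seed = as.integer(seed),
                 slide_id = slide_id),
            class = "synthetic_slide_spec")
}

# draw filled disks ("nuclei") into a h x w x 3 array, in place semantics
draw_blobs <- function(px, n_blobs, r_range, col, h, w) {
  if (n_blobs < 1L) return(px)
  cx <- stats::runif(n_blobs, 1, w)
  cy <- stats::runif(n_blobs, 1, h)
  rr <- stats::runif(n_blobs, r_range[1], r_range[2])
  for (k in seq_len(n_blobs)) {
    x0 <- max(1L, floor(cx[k] - rr[k])); x1 <- min(w, ceiling(cx[k] + rr[k]))
    y0 <- max(1L, floor(cy[k] - rr[k])); y1 <- min(h, ceiling(cy[k] + rr[k]))
    xs <- x0:x1; ys <- y0:y1
    dist2 <- outer((ys - cy[k])^2, (xs - cx[k])^2, "+")
    mask <- dist2 <= rr[k]^2
    if (!any(mask)) next
    idx <- which(mask, arr.ind = TRUE)
    rows <- ys[idx[, 1L]]; cols <- xs[idx[, 2L]]
    for (ch in 1:3) {
      lin <- cbind(rows, cols, ch)
      px[lin] <- col[ch]
    }
  }
  px
}

#' Generate a synthetic slide with planted ground truth
#'
#' Renders the image described by a [synthetic_slide_spec()] and records,
#' per grid cell, whether it is tissue and whether it carries the positive
#' cue. Background cells are rendered near-white (mean gray above the
#' Stage-1 drop threshold); tissue cells are rendered well below it.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return a list of class `slide_image` with elements `slide_id`, `pixels`
#'   (numeric `height x width x 3` array, 8-bit 0..255 scale), `width_px`,
#'   `height_px`, `label`, `tile_px`, `microns_per_pixel`, and `mask` — a
#'   data frame with one row per grid cell (`tile_row`, `tile_col`,
#'   0-based `origin_x`/`origin_y`, logical `is_tissue`, `is_positive`).
#' @examples
#' sl <- generate_synthetic_slide(
#'   synthetic_slide_spec(256, 192, tile_px = 64, tissue_fraction = 0.5,
#'                        seed = 3))
#' table(sl$mask$is_tissue)
#' @export
generate_synthetic_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  h <- spec$height_px; w <- spec$width_px; ts <- spec$tile_px
  n_rows <- h %/% ts; n_cols <- w %/% ts
  n_cells <- n_rows * n_cols

  withr::with_seed(spec$seed, {
    n_tissue <- round(spec$tissue_fraction * n_cells)
    tissue_cells <- sort(sample.int(n_cells, n_tissue))
    n_pos <- round(spec$positive_tile_fraction * n_tissue)
    pos_cells <- if (n_pos > 0) sort(sample(tissue_cells, n_pos)) else integer(0)

    # background: near-white with slight sensor noise, equal channels
    bg_val <- spec$background_brightness * 255
    px <- array(stats::rnorm(h * w * 3, mean = bg_val, sd = 4), dim = c(h, w, 3))

    # palettes: eosin-pink tissue; positive cue = purple hue shift + denser,
    # darker nuclei
    base_neg <- c(222, 162, 190)
    base_pos <- c(192, 132, 202)
    nuc_neg <- c(88, 70, 150)
    nuc_pos <- c(62, 44, 120)
    blob_density_neg <- 18   # nuclei per 64x64 px of tissue
    blob_density_pos <- 38

    cell_id <- 0L
    mask <- vector("list", n_cells)
    for (r in seq_len(n_rows)) {
      for (cc in seq_len(n_cols)) {
        cell_id <- cell_id + 1L
        y0 <- (r - 1L) * ts; x0 <- (cc - 1L) * ts
        is_t <- cell_id %in% tissue_cells
        is_p <- cell_id %in% pos_cells
        mask[[cell_id]] <- data.frame(tile_row = r - 1L, tile_col = cc - 1L,
                                      origin_x = x0, origin_y = y0,
                                      is_tissue = is_t, is_positive = is_p)
        if (!is_t) next
        base <- if (is_p) base_pos else base_neg
        nuc <- if (is_p) nuc_pos else nuc_neg
        dens <- if (is_p) blob_density_pos else blob_density_neg
        cell <- array(0, dim = c(ts, ts, 3))
        for (ch in 1:3) {
          cell[, , ch] <- base[ch] + stats::rnorm(ts * ts, sd = 7)
        }
        n_blobs <- stats::rpois(1L, dens * (ts / 64)^2)
        cell <- draw_blobs(cell, n_blobs, r_range = c(2.5, 5.5) * ts / 64,
                           col = nuc, h = ts, w = ts)
        px[(y0 + 1L):(y0 + ts), (x0 + 1L):(x0 + ts), ] <- cell
      }
    }
    px <- pmin(pmax(px, 0), 255)
    structure(list(slide_id = spec$slide_id,
                   pixels = px,
                   width_px = w, height_px = h,
                   label = spec$slide_label,
                   tile_px = ts,
                   microns_per_pixel = NA_real_,
                   mask = do.call(rbind, mask)),
              class = "slide_image")
  })
}

#' @export
print.slide_image <- function(x, ...) {
  cat("<slide_image>", x$slide_id, "\n",
      " ", x$width_px, "x", x$height_px, "px, label =",
      if (is.null(x$label) || is.na(x$label)) "NA" else x$label, "\n")
  if (!is.null(x$mask)) {
    cat("  grid cells:", nrow(x$mask),
        "(tissue:", sum(x$mask$is_tissue),
        ", positive-cue:", sum(x$mask$is_positive), ")\n")
  }
  invisible(x)
}

#' Generate a cohort of synthetic slides
#'
#' Convenience wrapper producing `n_slides` slides with balanced labels:
#' positive slides carry the positive cue in `positive_tile_fraction` of
#' their tissue cells, negative slides carry none. Per-slide seeds are
#' derived deterministically from `seed`.
#'
#' @param n_slides number of slides.
#' @param positive_slide_fraction fraction of slides labelled positive.
#' @param positive_tile_fraction cue-bearing fraction of tissue tiles in
#'   positive slides.
#' @param width_px,height_px,tile_px,tissue_fraction,background_brightness
#'   per-slide geometry and appearance, as in [synthetic_slide_spec()].
#' @param seed master seed for the cohort.
#' @return list of `slide_image` objects.
#' @export
generate_synthetic_cohort <- function(n_slides, positive_slide_fraction = 0.5,
                                      positive_tile_fraction = 0.6,
                                      width_px = 512L, height_px = 320L,
                                      tile_px = 64L, tissue_fraction = 0.6,
                                      background_brightness = 0.95,
                                      seed = 1L) {
  n_pos <- round(positive_slide_fraction * n_slides)
  # interleave positives evenly so any contiguous train/test split keeps
  # the cohort's class balance
  i <- seq_len(n_slides)
  labels <- as.integer(floor(i * n_pos / n_slides) >
                         floor((i - 1) * n_pos / n_slides))
  lapply(seq_len(n_slides), function(i) {
    generate_synthetic_slide(synthetic_slide_spec(
      width_px = width_px, height_px = height_px, tile_px = tile_px,
      background_brightness = background_brightness,
      tissue_fraction = tissue_fraction,
      positive_tile_fraction = if (labels[i] == 1L) positive_tile_fraction else 0,
      slide_label = labels[i],
      seed = seed * 10000L + i,
      slide_id = sprintf("slide_%03d", i)))
  })
}
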