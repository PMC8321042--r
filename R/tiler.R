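#' Mean grayscale brightness of an RGB raster
#'
#' Per-pixel luminance (Rec. 601 luma, 0.299 R + 0.587 G + 0.114 B)
#' averaged over the raster and scaled to [0, 1]: 0 is black, 1 is white.
#' This is the statistic the background filter thresholds.
#'
#' @param pixels a `height x width x 3` numeric array on the 0..255 scale,
#'   a grayscale matrix, or a `tile` / `slide_image` object.
#' @param weights length-3 RGB luma weights; Rec. 601 by default.
#' @return scalar in [0, 1].
#' @examples
#' mean_grayscale(array(255, c(4, 4, 3)))  # 1
#' mean_grayscale(array(128, c(4, 4, 3)))  # 128/255
#' @export
mean_grayscale <- function(pixels, weights = c(0.299, 0.587, 0.114)) {
  if (inherits(pixels, c("tile", "slide_image"))) pixels <- pixels$pixels
  stopifnot(length(weights) == 3)
  if (length(dim(pixels)) == 3L) {
    lum <- weights[1] * pixels[, , 1] + weights[2] * pixels[, , 2] +
      weights[3] * pixels[, , 3]
  } else {
    lum <- pixels
  }
  mean(lum) / 255
}

new_tile <- function(slide_id, origin_x, origin_y, size_px, pixels,
                     gray_weights = c(0.299, 0.587, 0.114)) {
  structure(list(slide_id = slide_id,
                 origin_x = as.integer(origin_x),
                 origin_y = as.integer(origin_y),
                 size_px = as.integer(size_px),
                 pixels = pixels,
                 mean_gray = mean_grayscale(pixels, gray_weights)),
            class = "tile")
}

#' @export
print.tile <- function(x, ...) {
  cat(sprintf("<tile> %s @ (%d,%d) %dpx mean_gray=%.3f\n",
              x$slide_id, x$origin_x, x$origin_y, x$size_px, x$mean_gray))
  invisible(x)
}

#' Decompose a slide into fixed-size tiles on a regular grid
#'
#' Cuts square tiles at origins `0, stride, 2*stride, ...` along each axis,
#' keeping a tile only if it fits entirely inside the image (partial tiles
#' at the right/bottom borders are discarded, no padding). Coordinates are
#' 0-based with half-open pixel intervals `[origin, origin + size)`. The
#' default `stride = tile_size` gives the non-overlapping ("no stride")
#' decomposition; `stride = tile_size / 2` gives the half-overlapping grid
#' used for 2048x1536 images cut into 512-px tiles at stride 256 (35 tiles).
#'
#' @param image a `slide_image` (or any list with `pixels`, `slide_id`,
#'   `width_px`, `height_px`).
#' @param tile_size tile side in pixels (default 512).
#' @param stride grid step in pixels; defaults to `tile_size`.
#' @param gray_weights luma weights handed to [mean_grayscale()].
#' @return list of `tile` objects in row-major grid order (possibly empty
#'   when the image is smaller than one tile). The count equals
#'   `floor((W - tile_size)/stride + 1) * floor((H - tile_size)/stride + 1)`
#'   when both dimensions are at least `tile_size`, else 0.
#' @examples
#' sl <- generate_synthetic_slide(synthetic_slide_spec(256, 192, tile_px = 64))
#' length(extract_tiles(sl, 64))       # 12 tiles (4 x 3)
#' length(extract_tiles(sl, 64, 32))   # 35 tiles (7 x 5)
#' @export
extract_tiles <- function(image, tile_size = 512L, stride = tile_size,
                          gray_weights = c(0.299, 0.587, 0.114)) {
  stopifnot(tile_size >= 1, stride >= 1)
  w <- image$width_px; h <- image$height_px
  if (is.null(w)) { d <- dim(image$pixels); h <- d[1]; w <- d[2] }
  if (w < tile_size || h < tile_size) return(list())
  xs <- seq.int(0L, w - tile_size, by = stride)
  ys <- seq.int(0L, h - tile_size, by = stride)
  out <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (y in ys) {
    for (x in xs) {
      k <- k + 1L
      out[[k]] <- new_tile(image$slide_id, x, y, tile_size,
                           image$pixels[(y + 1L):(y + tile_size),
                                        (x + 1L):(x + tile_size), , drop = FALSE],
                           gray_weights)
    }
  }
  out
}

#' Closed-form tile-grid count
#'
#' Number of complete tiles a regular grid yields:
#' `floor((W - tile_size)/stride + 1) * floor((H - tile_size)/stride + 1)`
#' when both dimensions are at least `tile_size`, else 0. Agrees with
#' `length(extract_tiles(...))` by construction.
#'
#' @param width_px,height_px image dimensions.
#' @param tile_size tile side in pixels.
#' @param stride grid step in pixels.
#' @return non-negative integer count.
#' @examples
#' tile_grid_count(2048, 1536, 512, 256)  # 35
#' @export
tile_grid_count <- function(width_px, height_px, tile_size = 512L,
                            stride = tile_size) {
  stopifnot(tile_size >= 1, stride >= 1)
  if (width_px < tile_size || height_px < tile_size) return(0L)
  as.integer((floor((width_px - tile_size) / stride) + 1) *
               (floor((height_px - tile_size) / stride) + 1))
}

#' Drop background tiles by mean grayscale
#'
#' Keeps exactly the tiles whose mean grayscale brightness is less than or
#' equal to `threshold` (tiles strictly brighter than the threshold are
#' dropped as background), preserving input order. Idempotent.
#'
#' @param tiles list of `tile` objects.
#' @param threshold brightness cutoff in [0, 1]; default 0.8.
#' @return the kept sublist.
#' @export
filter_background <- function(tiles, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  Filter(function(t) t$mean_gray <= threshold, tiles)
}

#' Tile manifest as a data frame
#'
#' @param tiles list of `tile` objects.
#' @param kept optional subset of `tiles` that survived filtering; when
#'   supplied a `kept_flag` column marks membership.
#' @return data frame with columns `slide_id`, `origin_x`, `origin_y`,
#'   `size_px`, `mean_gray` (and `kept_flag` when `kept` is given).
#' @export
tile_manifest <- function(tiles, kept = NULL) {
  df <- data.frame(
    slide_id = vapply(tiles, `[[`, character(1), "slide_id"),
    origin_x = vapply(tiles, `[[`, integer(1), "origin_x"),
    origin_y = vapply(tiles, `[[`, integer(1), "origin_y"),
    size_px = vapply(tiles, `[[`, integer(1), "size_px"),
    mean_gray = vapply(tiles, `[[`, numeric(1), "mean_gray"))
  if (!is.null(kept)) {
    key <- function(ts) paste(vapply(ts, `[[`, character(1), "slide_id"),
                              vapply(ts, `[[`, integer(1), "origin_x"),
                              vapply(ts, `[[`, integer(1), "origin_y"))
    df$kept_flag <- key(tiles) %in% key(kept)
  }
  df
}

#' Read a rasterized slide from PNG or TIFF
#'
#' Single-plane RGB rasters only; pixel values are returned on the 8-bit
#' 0..255 scale regardless of the on-disk encoding.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param slide_id identifier; defaults to the file stem.
#' @param label optional binary HER2 label.
#' @param microns_per_pixel optional resolution metadata, recorded as-is.
#' @return a `slide_image`.
#' @export
read_slide_image <- function(path, slide_id = sub("\\.[^.]+$", "", basename(path)),
                             label = NA_integer_, microns_per_pixel = NA_real_) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported slide format: .", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- raw * 255
  structure(list(slide_id = slide_id, pixels = px,
                 width_px = dim(px)[2], height_px = dim(px)[1],
                 label = label, tile_px = NA_integer_,
                 microns_per_pixel = microns_per_pixel, mask = NULL),
            class = "slide_image")
}

#' Write a slide image to PNG or TIFF
#'
#' @param image a `slide_image`.
#' @param path destination ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path) {
  ext <- tolower(sub(".*\\.", "", path))
  arr <- image$pixels / 255
  switch(ext,
         png = png::writePNG(arr, path),
         tif = ,
         tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         stop("unsupported slide format: .", ext))
  invisible(path)
}
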