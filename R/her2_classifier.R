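#' Per-slide vector of tile HER2 probabilities
#'
#' The contract between the imaging half of the cascade and the
#' feature/aggregation half: one probability per surviving tile of one
#' slide, in stable (row-major grid) order.
#'
#' @param slide_id slide identifier.
#' @param p numeric vector of probabilities in [0, 1], length >= 1.
#' @param tile_keys optional data frame with `origin_x`, `origin_y` per
#'   tile (recycled rows allowed); defaults to sequential keys.
#' @return an object of class `slide_probabilities`.
#' @export
slide_probabilities <- function(slide_id, p, tile_keys = NULL) {
  p <- as.numeric(p)
  if (length(p) < 1L) {
    stop("slide ", sQuote(slide_id), ": empty probability vector ",
         "(no tiles survived filtering)")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("slide ", sQuote(slide_id), ": probabilities must lie in [0, 1]")
  }
  if (is.null(tile_keys)) {
    tile_keys <- data.frame(origin_x = seq_along(p) - 1L, origin_y = 0L)
  }
  if (nrow(tile_keys) != length(p)) {
    stop("slide ", sQuote(slide_id), ": tile_keys length mismatch")
  }
  structure(list(slide_id = slide_id, p = p, tile_keys = tile_keys),
            class = "slide_probabilities")
}

#' @export
print.slide_probabilities <- function(x, ...) {
  cat(sprintf("<slide_probabilities> %s: %d tiles, mean p = %.3f\n",
              x$slide_id, length(x$p), mean(x$p)))
  invisible(x)
}

#' Weakly label tiles with their slide's HER2 status
#'
#' The multiple-instance labelling step: every tile inherits the binary
#' label of the slide it came from. Pixels and ordering are untouched.
#'
#' @param tiles list of `tile` objects.
#' @param slide_labels named vector or list mapping `slide_id` to 0/1.
#' @return list with elements `tiles` (unchanged) and `labels` (integer
#'   vector aligned with `tiles`).
#' @export
assign_slide_labels_to_tiles <- function(tiles, slide_labels) {
  if (length(tiles) == 0L) return(list(tiles = list(), labels = integer(0)))
  sids <- vapply(tiles, `[[`, character(1), "slide_id")
  missing <- setdiff(unique(sids), names(slide_labels))
  if (length(missing) > 0) {
    stop("no slide label for: ", paste(sQuote(missing), collapse = ", "))
  }
  labels <- as.integer(unlist(slide_labels[sids], use.names = FALSE))
  stopifnot(all(labels %in% c(0L, 1L)))
  list(tiles = tiles, labels = labels)
}

#' Configuration for the HER2 tile classifier
#'
#' Stage 3 presets. Training optimises cross-entropy with a one-cycle
#' learning-rate schedule; precision is the monitored metric, logged per
#' epoch (a precision "loss" is not differentiable, so it guides model
#' inspection rather than the gradient).
#'
#' @param backbone `"colorstat"` (desk preset) or `"resnet152"`
#'   (full-scale preset requiring an external feature provider).
#' @param epochs training epochs over the full network (default 3).
#' @param hidden hidden-layer sizes of the head.
#' @param lr_max peak one-cycle learning rate.
#' @param augmentation,augment_copies as in [tile_classifier_config()].
#' @param seed integer seed.
#' @return an object of class `her2_training_config`.
#' @export
her2_training_config <- function(backbone = "colorstat", epochs = 3L,
                                 hidden = c(32L, 16L), lr_max = 0.02,
                                 augmentation = default_augmentation,
                                 augment_copies = 1L, seed = 1L) {
  stopifnot(epochs >= 1, all(hidden >= 1))
  structure(list(backbone = match.arg(backbone, tile_backbones),
                 epochs = as.integer(epochs), hidden = as.integer(hidden),
                 lr_max = lr_max, augmentation = augmentation,
                 augment_copies = as.integer(augment_copies),
                 seed = as.integer(seed)),
            class = "her2_training_config")
}

#' Train the per-tile HER2 probability classifier
#'
#' Stage 3: trains on weakly labelled tiles (see
#' [assign_slide_labels_to_tiles()]) and exposes, through `predict()`, the
#' probability of the HER2-positive class for each tile — the `p_ij`
#' consumed by the feature stage. Class order is fixed as (negative = 0,
#' positive = 1) throughout.
#'
#' @param labelled output of [assign_slide_labels_to_tiles()], or a list
#'   with `tiles` and `labels`.
#' @param config a [her2_training_config()].
#' @return a `tile_classifier`.
#' @export
train_her2_classifier <- function(labelled, config = her2_training_config()) {
  fit_tile_classifier(labelled$tiles, labelled$labels,
                      backbone = config$backbone, hidden = config$hidden,
                      head_epochs = 0L, full_epochs = config$epochs,
                      lr_max = config$lr_max,
                      augmentation = config$augmentation,
                      augment_copies = config$augment_copies,
                      seed = config$seed, schedule = "onecycle",
                      monitor = "precision",
                      class_levels = c("HER2-negative", "HER2-positive"))
}

#' Predict per-slide tile probability vectors
#'
#' Groups tiles by slide and applies the tile model, returning one
#' `slide_probabilities` per slide with tiles in their original (row-major
#' grid) order.
#'
#' @param model a `tile_classifier`, or an oracle function mapping a tile
#'   list to probabilities.
#' @param tiles list of `tile` objects from one or more slides.
#' @return named list of `slide_probabilities`, keyed and ordered by first
#'   appearance of each slide.
#' @export
predict_slide_probabilities <- function(model, tiles) {
  if (length(tiles) == 0L) stop("no tiles to predict on")
  sids <- vapply(tiles, `[[`, character(1), "slide_id")
  p <- if (is.function(model)) model(tiles) else predict(model, tiles)
  stopifnot(length(p) == length(tiles))
  out <- lapply(unique(sids), function(sid) {
    idx <- which(sids == sid)
    slide_probabilities(sid, p[idx],
                        tile_keys = data.frame(
                          origin_x = vapply(tiles[idx], `[[`, integer(1), "origin_x"),
                          origin_y = vapply(tiles[idx], `[[`, integer(1), "origin_y")))
  })
  names(out) <- unique(sids)
  out
}

#' Write per-tile probabilities to CSV
#'
#' Columns `slide_id`, `origin_x`, `origin_y`, `p` — the standalone entry
#' point for the feature and aggregation stages.
#'
#' @param probs list of `slide_probabilities`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_slide_probabilities <- function(probs, path) {
  rows <- do.call(rbind, lapply(probs, function(sp) {
    data.frame(slide_id = sp$slide_id,
               origin_x = sp$tile_keys$origin_x,
               origin_y = sp$tile_keys$origin_y,
               p = sp$p)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read per-tile probabilities from CSV
#'
#' @param path CSV with columns `slide_id`, `origin_x`, `origin_y`, `p`
#'   (or `probability`).
#' @return named list of `slide_probabilities`.
#' @export
read_slide_probabilities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"p" %in% names(df) && "probability" %in% names(df)) {
    df$p <- df$probability
  }
  if (!"origin_x" %in% names(df) && "tile_col" %in% names(df)) {
    df$origin_x <- df$tile_col; df$origin_y <- df$tile_row
  }
  out <- lapply(split(df, factor(df$slide_id, levels = unique(df$slide_id))),
                function(d) slide_probabilities(
                  d$slide_id[1], d$p,
                  tile_keys = data.frame(origin_x = d$origin_x,
                                         origin_y = d$origin_y)))
  out[unique(df$slide_id)]
}
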