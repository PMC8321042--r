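#' Collapse the four BACH tile classes to binary cancer labels
#'
#' Maps "normal" and "benign" to "no cancer", and "in situ carcinoma" and
#' "invasive carcinoma" to "cancer". Any other string is rejected — there
#' is deliberately no silent default.
#'
#' @param raw_label character vector of BACH class names.
#' @return character vector over `c("no cancer", "cancer")`.
#' @examples
#' collapse_bach_labels(c("benign", "invasive carcinoma"))
#' @export
collapse_bach_labels <- function(raw_label) {
  map <- c("normal" = "no cancer", "benign" = "no cancer",
           "in situ carcinoma" = "cancer", "invasive carcinoma" = "cancer")
  unknown <- setdiff(unique(raw_label), names(map))
  if (length(unknown) > 0) {
    stop("unknown BACH label(s): ", paste(sQuote(unknown), collapse = ", "),
         "; expected one of ", paste(sQuote(names(map)), collapse = ", "))
  }
  unname(map[raw_label])
}

#' Configuration for the cancer-tile pre-filter classifier
#'
#' Two-phase fine-tuning: `head_epochs` epochs updating only the output
#' layer, then `full_epochs` epochs updating the whole network. The
#' full-scale preset is a DenseNet-201-class pretrained backbone; the
#' desk-scale `"colorstat"` backbone (default) extracts colour statistics
#' and trains in seconds.
#'
#' @param backbone one of `"colorstat"`, `"densenet201"`, `"resnet152"`.
#' @param head_epochs,full_epochs epochs for each phase (defaults 3 and 3).
#' @param hidden hidden-layer sizes of the classification head.
#' @param lr_max peak learning rate of the one-cycle schedule.
#' @param augmentation character subset of
#'   `c("flips","rotations","zoom","warp","luminosity","contrast")`.
#' @param augment_copies augmented copies of the training set to append.
#' @param seed integer seed.
#' @return an object of class `tile_classifier_config`.
#' @export
tile_classifier_config <- function(backbone = "colorstat",
                                   head_epochs = 3L, full_epochs = 3L,
                                   hidden = c(32L, 16L), lr_max = 0.02,
                                   augmentation = default_augmentation,
                                   augment_copies = 1L, seed = 1L) {
  stopifnot(head_epochs >= 0, full_epochs >= 0, all(hidden >= 1))
  structure(list(backbone = match.arg(backbone, tile_backbones),
                 head_epochs = as.integer(head_epochs),
                 full_epochs = as.integer(full_epochs),
                 hidden = as.integer(hidden), lr_max = lr_max,
                 augmentation = augmentation,
                 augment_copies = as.integer(augment_copies),
                 seed = as.integer(seed)),
            class = "tile_classifier_config")
}

#' Train the binary cancer / no-cancer tile classifier
#'
#' Stage 2B of the cascade. Tiles are labelled (after
#' [collapse_bach_labels()] when starting from the four-class scheme) and a
#' classifier is fine-tuned in two phases with the configured
#' augmentations. With both epoch counts zero the returned model simply
#' emits the training prior, so the surrounding pipeline still runs.
#'
#' @param tiles list of `tile` objects.
#' @param labels binary labels, either 0/1 or `"no cancer"`/`"cancer"`;
#'   both classes must be present.
#' @param config a [tile_classifier_config()].
#' @return a `tile_classifier`; `predict()` returns the cancer probability.
#' @export
train_cancer_classifier <- function(tiles, labels,
                                    config = tile_classifier_config()) {
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("no cancer", "cancer"))
    if (length(bad)) stop("unknown binary label(s): ",
                          paste(sQuote(bad), collapse = ", "))
    labels <- as.integer(labels == "cancer")
  }
  fit_tile_classifier(tiles, labels,
                      backbone = config$backbone, hidden = config$hidden,
                      head_epochs = config$head_epochs,
                      full_epochs = config$full_epochs,
                      lr_max = config$lr_max,
                      augmentation = config$augmentation,
                      augment_copies = config$augment_copies,
                      seed = config$seed, monitor = "accuracy",
                      class_levels = c("no cancer", "cancer"))
}

#' Keep only tiles classified as containing cancer
#'
#' Applies the pre-filter: a tile is kept when its predicted cancer
#' probability is at least `threshold` (0.5, i.e. the argmax of the two
#' classes; a tie at exactly 0.5 counts as cancer). Order is preserved and
#' kept/removed counts are reported via `message()`.
#'
#' @param model a `tile_classifier` (or any object with a `predict` method
#'   returning cancer probabilities for a tile list — an oracle function of
#'   the synthetic ground truth works too).
#' @param tiles list of `tile` objects.
#' @param threshold decision cutoff, default 0.5.
#' @param quiet suppress the count message.
#' @return the kept sublist, with a `probabilities` attribute holding the
#'   predicted cancer probability of every input tile.
#' @export
filter_cancer_tiles <- function(model, tiles, threshold = 0.5, quiet = FALSE) {
  if (length(tiles) == 0L) return(list())
  p <- if (is.function(model)) model(tiles) else predict(model, tiles)
  stopifnot(length(p) == length(tiles), all(p >= 0), all(p <= 1))
  keep <- p >= threshold
  if (!quiet) {
    message(sprintf("cancer filter: kept %d / %d tiles (removed %.2f%%)",
                    sum(keep), length(tiles), 100 * mean(!keep)))
  }
  out <- tiles[keep]
  attr(out, "probabilities") <- p
  out
}
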