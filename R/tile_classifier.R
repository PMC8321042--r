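# Shared machinery for the two image-level classifiers (cancer pre-filter,
# HER2 tile classifier). A backbone maps a tile's pixel array to a feature
# vector; a fully-connected head (R/mlp.R) maps features to a class
# probability. The "colorstat" desk-scale backbone summarises the tile by
# colour statistics, which is sufficient to learn the synthetic generator's
# hue-shift + blob-density cue; "densenet201" and "resnet152" are the
# documented full-scale presets and require an external feature provider.

tile_backbones <- c("colorstat", "densenet201", "resnet152")

# colour-statistic features; px on 0..255 scale, h x w x 3
colorstat_features <- function(px) {
  r <- px[, , 1] / 255; g <- px[, , 2] / 255; b <- px[, , 3] / 255
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  hue <- hsv[1, ] * 2 * pi
  c(mean_r = mean(r), mean_g = mean(g), mean_b = mean(b),
    sd_r = stats::sd(r), sd_g = stats::sd(g), sd_b = stats::sd(b),
    mean_gray = mean(lum),
    dark_frac = mean(lum < 0.45),        # nuclear-blob coverage proxy
    mid_frac = mean(lum >= 0.45 & lum < 0.7),
    sat_mean = mean(hsv[2, ]),
    val_mean = mean(hsv[3, ]),
    hue_cos = mean(cos(hue)), hue_sin = mean(sin(hue)))
}

backbone_features <- function(tiles, backbone = "colorstat") {
  backbone <- match.arg(backbone, tile_backbones)
  if (backbone != "colorstat") {
    stop("backbone '", backbone, "' is a full-scale preset requiring an ",
         "external pretrained feature provider; use the 'colorstat' desk ",
         "preset or supply features directly")
  }
  t(vapply(tiles, function(t) colorstat_features(t$pixels),
           numeric(length(colorstat_features(array(0, c(2, 2, 3)))))))
}

# photometric/geometric augmentation of one tile's pixels; flags per config
augment_tile_pixels <- function(px, flags) {
  if ("flips" %in% flags && stats::runif(1) < 0.5) {
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  }
  if ("rotations" %in% flags) {
    k <- sample(0:3, 1L)
    for (i in seq_len(k)) px <- aperm(px[rev(seq_len(dim(px)[1])), , , drop = FALSE],
                                      c(2, 1, 3))
  }
  if ("luminosity" %in% flags) {
    px <- px + stats::runif(1, -15, 15)
  }
  if ("contrast" %in% flags) {
    m <- mean(px)
    px <- (px - m) * stats::runif(1, 0.9, 1.1) + m
  }
  # zoom / warp flags are accepted but are no-ops for the colorstat
  # backbone, whose features are invariant to them by construction
  pmin(pmax(px, 0), 255)
}

default_augmentation <- c("flips", "rotations", "zoom", "warp",
                          "luminosity", "contrast")

# Generic two-phase trainer shared by both classifiers.
fit_tile_classifier <- function(tiles, labels, backbone, hidden,
                                head_epochs, full_epochs, lr_max,
                                augmentation, augment_copies, seed,
                                schedule = "onecycle", monitor = "none",
                                class_levels) {
  y <- as.numeric(labels)
  stopifnot(length(tiles) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both classes are required")
  }
  withr::with_seed(seed, {
    aug_tiles <- tiles; aug_y <- y
    if (length(augmentation) > 0 && augment_copies > 0) {
      for (k in seq_len(augment_copies)) {
        aug_tiles <- c(aug_tiles, lapply(tiles, function(t) {
          t$pixels <- augment_tile_pixels(t$pixels, augmentation); t
        }))
        aug_y <- c(aug_y, y)
      }
    }
    x <- backbone_features(aug_tiles, backbone)
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd); scale[scale < 1e-8] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")

    par <- mlp_init(ncol(xs), hidden, seed = seed + 1L)
    log_head <- numeric(0); log_full <- numeric(0)
    if (head_epochs > 0) {
      fit <- mlp_train(par, xs, aug_y, epochs = head_epochs, lr_max = lr_max,
                       schedule = schedule, phase = "head", monitor = monitor)
      par <- fit$par; log_head <- fit$log
    }
    if (full_epochs > 0) {
      fit <- mlp_train(par, xs, aug_y, epochs = full_epochs, lr_max = lr_max,
                       schedule = schedule, phase = "full", monitor = monitor)
      par <- fit$par; log_full <- fit$log
    }
    prior <- mean(y)
    structure(list(par = par, backbone = backbone, hidden = hidden,
                   center = center, scale = scale,
                   trained = (head_epochs + full_epochs) > 0,
                   prior = prior, class_levels = class_levels,
                   metric_log = list(head = log_head, full = log_full),
                   n_train = length(tiles), seed = seed),
              class = "tile_classifier")
  })
}

#' Predict class probabilities for tiles
#'
#' Returns the probability of the positive class (second level of the
#' model's `class_levels`) for each tile. Inference is deterministic. An
#' untrained model (zero epochs) returns its training-set prior for every
#' tile.
#'
#' @param object a `tile_classifier` from [train_cancer_classifier()] or
#'   [train_her2_classifier()].
#' @param tiles list of `tile` objects.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.tile_classifier <- function(object, tiles, ...) {
  if (length(tiles) == 0L) return(numeric(0))
  if (!object$trained) return(rep(object$prior, length(tiles)))
  x <- backbone_features(tiles, object$backbone)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  mlp_predict(object$par, xs)
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat("<tile_classifier>", x$backbone, "backbone,",
      paste(x$hidden, collapse = "-"), "hidden units\n",
      " classes:", paste(x$class_levels, collapse = " / "),
      "| trained on", x$n_train, "tiles\n")
  if (length(x$metric_log$full)) {
    cat("  final monitored metric:",
        round(utils::tail(stats::na.omit(x$metric_log$full), 1), 3), "\n")
  }
  invisible(x)
}
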