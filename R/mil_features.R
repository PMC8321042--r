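# Stage 4: slide-level multiple-instance features from the tile
# probability vector p_1..p_T of one slide.
#
#   G(p)     = 1 if p >= 0.5                       (tile positivity indicator)
#   P1* (s)  = mean(p)                              P1 = 1 iff P1* >= 0.5
#   P2 (s)   = 1 iff mean(p * G(p)) >= 0.66         (masked mean over ALL T)
#   P3 (s)   = 1 iff mean(G(p)) >= 0.35
#   Fh (s)   = fraction of p in [h, h+0.1), h in {0.5,...,0.9};
#              the top bin [0.9, 1.0] is closed so p = 1 is counted.
#
# All comparisons are >= exactly; no tolerance is added at the thresholds.

check_prob_vector <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("empty probability vector: no tiles for this slide")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p
}

#' Tile positivity indicator G
#'
#' `G(p) = 1` when `p >= 0.5`, else 0. Vectorised.
#'
#' @param p probability (or vector of probabilities) in [0, 1].
#' @return integer 0/1 of the same length.
#' @examples
#' indicator_G(c(0.4999, 0.5, 1))  # 0 1 1
#' @export
indicator_G <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  as.integer(p >= 0.5)
}

#' Positivity index P1 (mean tile probability)
#'
#' @param p tile probability vector of one slide, length >= 1.
#' @param threshold binarisation cutoff (default 0.5).
#' @return list with `P1_star` (the non-binarised mean) and binary `P1`.
#' @examples
#' positivity_P1(c(0.9, 0.7, 0.2))  # P1_star 0.6, P1 = 1
#' @export
positivity_P1 <- function(p, threshold = 0.5) {
  p <- check_prob_vector(p)
  P1_star <- mean(p)
  list(P1_star = P1_star, P1 = as.integer(P1_star >= threshold))
}

#' Positivity index P2 (masked mean)
#'
#' Mean over all T tiles of `p * G(p)` — tiles below 0.5 contribute 0 but
#' still count in the denominator — thresholded at 0.66. (The denominator
#' is T, per the defining formula; `prose_variant = TRUE` divides by the
#' number of super-threshold tiles instead, the alternative reading of the
#' accompanying prose.)
#'
#' @param p tile probability vector of one slide.
#' @param threshold decision cutoff (default 0.66).
#' @param prose_variant divide by the super-threshold tile count instead
#'   of T; default `FALSE`.
#' @return binary 0/1.
#' @examples
#' positivity_P2(c(1, 1, 0))            # 2/3 >= 0.66 -> 1
#' positivity_P2(c(0.9, 0.9, 0.1, 0.1)) # 0.45 -> 0
#' @export
positivity_P2 <- function(p, threshold = 0.66, prose_variant = FALSE) {
  p <- check_prob_vector(p)
  g <- indicator_G(p)
  m <- if (prose_variant) {
    if (sum(g) == 0L) 0 else sum(p * g) / sum(g)
  } else {
    mean(p * g)
  }
  as.integer(m >= threshold)
}

#' Positivity index P3 (positive-tile fraction)
#'
#' 1 iff at least `threshold` (default 35%) of the slide's tiles have
#' probability at least 0.5.
#'
#' @param p tile probability vector of one slide.
#' @param threshold fraction cutoff (default 0.35).
#' @return binary 0/1.
#' @examples
#' positivity_P3(c(0.6, 0.6, 0.4))  # 2/3 -> 1
#' @export
positivity_P3 <- function(p, threshold = 0.35) {
  p <- check_prob_vector(p)
  as.integer(mean(indicator_G(p)) >= threshold)
}

#' Probability-histogram frequency Fh
#'
#' Fraction of the slide's tile probabilities in `[h, h + 0.1)`, for
#' `h` in {0.5, 0.6, 0.7, 0.8, 0.9}. By default the top bin is closed,
#' `[0.9, 1.0]`, so a certain-positive tile (p = 1) is counted; set
#' `closed_top = FALSE` for the strictly half-open variant.
#'
#' @param p tile probability vector of one slide.
#' @param h bin lower edge, one of 0.5, 0.6, 0.7, 0.8, 0.9.
#' @param closed_top include 1.0 in the top bin (default `TRUE`).
#' @return fraction in [0, 1].
#' @examples
#' frequency_Fh(c(0.55, 0.95, 0.30), 0.5)  # 1/3
#' frequency_Fh(1.0, 0.9)                  # 1
#' @export
frequency_Fh <- function(p, h, closed_top = TRUE) {
  p <- check_prob_vector(p)
  valid_h <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  if (length(h) != 1L || !any(abs(h - valid_h) < 1e-12)) {
    stop("h must be one of ", paste(valid_h, collapse = ", "))
  }
  upper <- h + 0.1
  top_bin <- isTRUE(closed_top) && abs(h - 0.9) < 1e-12
  in_bin <- p >= h & (p < upper | (if (top_bin) p <= 1 else FALSE))
  mean(in_bin)
}

#' Compute all slide-level features for one slide
#'
#' Assembles P1*, the three binary positivity indices and the five
#' histogram frequencies into one record — one row of the tabular
#' learner's training matrix plus the voting indices.
#'
#' @param sp a `slide_probabilities` (or a bare probability vector, in
#'   which case `slide_id` must be given).
#' @param slide_id identifier when `sp` is a bare vector.
#' @param closed_top top-bin rule for [frequency_Fh()].
#' @param p2_prose_variant see [positivity_P2()].
#' @return an object of class `slide_features`: a list with `slide_id`,
#'   `T` (tile count), `P1_star`, `P1`, `P2`, `P3` and `F` (named vector
#'   over h = 0.5 ... 0.9).
#' @examples
#' compute_features(slide_probabilities("s1", c(0.9, 0.7, 0.2)))
#' @export
compute_features <- function(sp, slide_id = NULL, closed_top = TRUE,
                             p2_prose_variant = FALSE) {
  if (inherits(sp, "slide_probabilities")) {
    p <- sp$p; slide_id <- sp$slide_id
  } else {
    p <- sp
    if (is.null(slide_id)) stop("slide_id required for a bare vector")
  }
  p <- check_prob_vector(p)
  p1 <- positivity_P1(p)
  hs <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  Fh <- vapply(hs, function(h) frequency_Fh(p, h, closed_top), numeric(1))
  names(Fh) <- sprintf("F%.1f", hs)
  structure(list(slide_id = slide_id, T = length(p),
                 P1_star = p1$P1_star, P1 = p1$P1,
                 P2 = positivity_P2(p, prose_variant = p2_prose_variant),
                 P3 = positivity_P3(p),
                 F = Fh),
            class = "slide_features")
}

#' @export
print.slide_features <- function(x, ...) {
  cat(sprintf("<slide_features> %s (T=%d): P1*=%.3f P1=%d P2=%d P3=%d\n",
              x$slide_id, x$T, x$P1_star, x$P1, x$P2, x$P3))
  cat("  F:", paste(sprintf("%s=%.3f", names(x$F), x$F), collapse = " "), "\n")
  invisible(x)
}

#' Feature table for a set of slides
#'
#' @param features list of `slide_features`.
#' @return data frame with columns `slide_id`, `T`, `P1_star`, `P1`, `P2`,
#'   `P3`, `F0.5` ... `F0.9`.
#' @export
slide_feature_table <- function(features) {
  do.call(rbind, lapply(features, function(f) {
    df <- data.frame(slide_id = f$slide_id, T = f$T, P1_star = f$P1_star,
                     P1 = f$P1, P2 = f$P2, P3 = f$P3)
    for (nm in names(f$F)) df[[nm]] <- unname(f$F[nm])
    df
  }))
}
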