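#' Majority vote over the three positivity indices
#'
#' The slide is called positive when at least two of P1, P2, P3 are 1.
#' With three binary voters no tie is possible. Vectorised over slides.
#'
#' @param P1,P2,P3 binary 0/1 vectors of equal length.
#' @return integer 0/1 vector.
#' @examples
#' majority_vote(1, 1, 0)  # 1
#' @export
majority_vote <- function(P1, P2, P3) {
  v <- cbind(P1, P2, P3)
  if (any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("P1, P2, P3 must all be binary 0/1")
  }
  as.integer(rowSums(v) >= 2)
}

#' Build the tabular learner's feature matrix
#'
#' One row per slide with the non-binarised mean probability P1* and the
#' five histogram frequencies F0.5 ... F0.9. The binary indices are
#' deliberately excluded by default (they add no information on top of
#' these features); `include_indices = TRUE` appends P1, P2, P3 for
#' experimentation.
#'
#' @param features list of `slide_features` (or a data frame from
#'   [slide_feature_table()]).
#' @param labels optional named vector mapping `slide_id` to 0/1; when
#'   supplied a label column `P` is appended (training mode) and every
#'   slide must be covered.
#' @param include_indices also include the binary P1, P2, P3 columns.
#' @return data frame keyed by unique `slide_id`.
#' @export
build_feature_matrix <- function(features, labels = NULL,
                                 include_indices = FALSE) {
  df <- if (is.data.frame(features)) features else slide_feature_table(features)
  if (anyDuplicated(df$slide_id)) {
    stop("duplicate slide_id(s): ",
         paste(sQuote(unique(df$slide_id[duplicated(df$slide_id)])),
               collapse = ", "))
  }
  cols <- c("slide_id", "P1_star", grep("^F0\\.", names(df), value = TRUE))
  if (include_indices) cols <- c(cols, "P1", "P2", "P3")
  out <- df[, cols]
  if (!is.null(labels)) {
    missing <- setdiff(df$slide_id, names(labels))
    if (length(missing) > 0) {
      stop("missing label(s) for: ", paste(sQuote(missing), collapse = ", "))
    }
    out$P <- as.integer(unlist(labels[df$slide_id], use.names = FALSE))
    stopifnot(all(out$P %in% c(0L, 1L)))
  }
  rownames(out) <- NULL
  out
}

#' Configuration for the slide-level tabular learner
#'
#' A fully-connected network on the feature row, with three hidden layers
#' of 500, 250 and 125 units by default. Optimised by cross-entropy;
#' accuracy is the monitored metric, logged per epoch.
#'
#' @param hidden_layers integer triple of hidden sizes.
#' @param epochs training epochs (default 200).
#' @param lr_max peak one-cycle learning rate.
#' @param seed integer seed.
#' @return an object of class `tabular_learner_config`.
#' @export
tabular_learner_config <- function(hidden_layers = c(500L, 250L, 125L),
                                   epochs = 200L, lr_max = 0.01, seed = 1L) {
  stopifnot(all(hidden_layers >= 1), epochs >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 epochs = as.integer(epochs), lr_max = lr_max,
                 seed = as.integer(seed)),
            class = "tabular_learner_config")
}

#' Train the slide-level tabular learner
#'
#' Stage 5B: learns to combine (P1*, F0.5 ... F0.9) into the final HER2
#' call, in place of the fixed majority-vote rule.
#'
#' @param rows training matrix from [build_feature_matrix()] with the
#'   label column `P`; both classes must be present.
#' @param config a [tabular_learner_config()].
#' @return an object of class `tabular_learner` with `predict` and `print`
#'   methods.
#' @export
train_tabular_learner <- function(rows, config = tabular_learner_config()) {
  if (!"P" %in% names(rows)) stop("training rows must carry the label column P")
  if (nrow(rows) < 2L) stop("at least two training rows are required")
  y <- rows$P
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both classes are required")
  }
  feat_cols <- setdiff(names(rows), c("slide_id", "P"))
  x <- as.matrix(rows[, feat_cols, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd); scale[scale < 1e-8] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  par <- mlp_init(ncol(xs), config$hidden_layers, seed = config$seed)
  fit <- mlp_train(par, xs, y, epochs = config$epochs, lr_max = config$lr_max,
                   schedule = "onecycle", phase = "full", monitor = "accuracy")
  structure(list(par = fit$par, feature_columns = feat_cols,
                 center = center, scale = scale,
                 hidden_layers = config$hidden_layers,
                 accuracy_log = fit$log, n_train = nrow(rows),
                 seed = config$seed),
            class = "tabular_learner")
}

#' Predict slide calls with the tabular learner
#'
#' Deterministic at inference: probability of the positive class and the
#' binary call at the 0.5 cutoff.
#'
#' @param object a `tabular_learner`.
#' @param rows feature rows from [build_feature_matrix()] (label column,
#'   if present, is ignored); must contain exactly the columns the model
#'   was trained on.
#' @param threshold call cutoff (default 0.5).
#' @param ... unused.
#' @return data frame with `slide_id`, `probability`, `call`.
#' @export
predict.tabular_learner <- function(object, rows, threshold = 0.5, ...) {
  missing <- setdiff(object$feature_columns, names(rows))
  if (length(missing) > 0) {
    stop("feature column(s) missing from rows: ",
         paste(sQuote(missing), collapse = ", "))
  }
  x <- as.matrix(rows[, object$feature_columns, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- mlp_predict(object$par, xs)
  data.frame(slide_id = if ("slide_id" %in% names(rows)) rows$slide_id
             else seq_len(nrow(rows)),
             probability = p,
             call = as.integer(p >= threshold))
}

#' @export
print.tabular_learner <- function(x, ...) {
  cat("<tabular_learner>", paste(x$hidden_layers, collapse = "-"),
      "hidden units on", length(x$feature_columns), "features\n",
      " trained on", x$n_train, "slides; final training accuracy:",
      round(utils::tail(x$accuracy_log, 1), 3), "\n")
  invisible(x)
}

#' Aggregate slide features into final HER2 calls
#'
#' Applies one of the two aggregation strategies to a feature table.
#'
#' @param features list of `slide_features` or a [slide_feature_table()]
#'   data frame.
#' @param method `"majority_vote"` or `"tabular"`.
#' @param model a trained `tabular_learner`, required for the tabular
#'   method.
#' @return data frame with `slide_id`, `call` (and `probability` for the
#'   tabular method).
#' @export
aggregate_slides <- function(features, method = c("majority_vote", "tabular"),
                             model = NULL) {
  method <- match.arg(method)
  df <- if (is.data.frame(features)) features else slide_feature_table(features)
  if (method == "majority_vote") {
    data.frame(slide_id = df$slide_id,
               call = majority_vote(df$P1, df$P2, df$P3))
  } else {
    if (is.null(model)) stop("the tabular method requires a trained model")
    pred <- predict(model, build_feature_matrix(df))
    data.frame(slide_id = pred$slide_id, call = pred$call,
               probability = pred$probability)
  }
}
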