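#' Classifier configuration
#'
#' Protocol parameters for the per-pixel random-forest classification: an
#' ensemble of decision trees each voting a class per pixel, with a fixed
#' number of candidate predictors drawn at each split. Defaults are 100
#' trees and 5 predictors per split (`mtry` is capped at the number of
#' available layers at training time).
#'
#' @param n_trees Number of trees (>= 1).
#' @param n_predictors_per_split Candidate predictors per split (>= 1).
#' @param seed Integer seed; training is deterministic under it.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 100, n_predictors_per_split = 5,
                              seed = 42L) {
  if (n_trees < 1 || n_predictors_per_split < 1)
    stop("n_trees and n_predictors_per_split must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 n_predictors_per_split = as.integer(n_predictors_per_split),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

sample_features <- function(stack, samples) {
  v <- stack$values
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  nb <- dim(v)[3L]
  X <- matrix(NA_real_, nrow(samples), nb)
  for (b in seq_len(nb))
    X[, b] <- v[, , b][cbind(samples$row, samples$col)]
  colnames(X) <- paste0("layer", seq_len(nb))
  X
}

#' Train the land-cover classifier
#'
#' Fits a random forest on the feature vectors extracted from the layer
#' stack at the training sample pixels. Samples falling on nodata pixels
#' are dropped with a warning; training on a single class is an error.
#'
#' @param stack Multi-layer [grid()] of predictor layers (the order of
#'   layers is the feature contract: prediction must use the same order).
#' @param train_samples Data frame with `row`, `col`, `class_code` (a
#'   [sample_points()] result; rows tagged `split == "train"` are used if a
#'   `split` column is present).
#' @param cfg A [classifier_config()].
#' @param legend Legend data frame `code,name` for the output map; defaults
#'   to the codes seen in training.
#' @return A model handle of class `lulc_model` wrapping the fitted forest
#'   plus the layer count, legend and configuration metadata.
#' @export
train_classifier <- function(stack, train_samples, cfg = classifier_config(),
                             legend = NULL) {
  stopifnot(is_grid(stack), inherits(cfg, "classifier_config"))
  s <- train_samples
  if (!is.null(s$split)) s <- s[s$split == "train", , drop = FALSE]
  X <- sample_features(stack, s)
  bad <- !stats::complete.cases(X)
  if (any(bad)) {
    warning(sum(bad), " training samples on nodata pixels dropped")
    s <- s[!bad, , drop = FALSE]
    X <- X[!bad, , drop = FALSE]
  }
  codes <- sort(unique(s$class_code))
  if (length(codes) < 2L)
    stop("training samples contain a single class; need at least 2")
  if (is.null(legend))
    legend <- data.frame(code = codes, name = as.character(codes),
                         stringsAsFactors = FALSE)
  y <- factor(s$class_code, levels = legend$code)
  y <- droplevels(y)
  mtry <- min(cfg$n_predictors_per_split, ncol(X))
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = cfg$n_trees,
                                   mtry = mtry)
  structure(list(rf = rf, n_layers = ncol(X), legend = legend,
                 config = cfg, mtry_used = mtry,
                 training_accuracy =
                   100 * mean(stats::predict(rf, X) == y)),
            class = "lulc_model")
}

#' @export
print.lulc_model <- function(x, ...) {
  cat(sprintf(
    "<lulc_model> %d trees, %d predictors/split (mtry %d), %d layers\n",
    x$config$n_trees, x$config$n_predictors_per_split, x$mtry_used,
    x$n_layers))
  cat(sprintf("  classes: %s\n", paste(x$legend$name, collapse = ", ")))
  invisible(x)
}

#' Predict a land-cover map
#'
#' Applies the fitted forest to every pixel of the stack: each tree votes
#' and the class with the most votes wins, ties broken deterministically in
#' favour of the lowest class code. Pixels with any nodata feature are
#' nodata in the output.
#'
#' @param model A `lulc_model` from [train_classifier()].
#' @param stack Multi-layer [grid()] with the same layer count and order as
#'   at training.
#' @return A [classmap()] of predicted class codes.
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(model, "lulc_model"), is_grid(stack))
  v <- stack$values
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  if (dim(v)[3L] != model$n_layers)
    stop("stack has ", dim(v)[3L], " layers but the model was trained on ",
         model$n_layers)
  nr <- dim(v)[1L]; nc <- dim(v)[2L]
  X <- matrix(v, nr * nc, model$n_layers)
  colnames(X) <- paste0("layer", seq_len(model$n_layers))
  ok <- stats::complete.cases(X)
  codes <- rep(NA_integer_, nr * nc)
  if (any(ok)) {
    votes <- stats::predict(model$rf, X[ok, , drop = FALSE], type = "vote",
                            norm.votes = FALSE)
    lev <- as.integer(colnames(votes))
    # argmax with lowest-code tie-break: max.col("first") on code-ordered cols
    o <- order(lev)
    codes[ok] <- lev[o][max.col(votes[, o, drop = FALSE],
                                ties.method = "first")]
  }
  classmap(matrix(codes, nr, nc), model$legend, stack$pixel_size,
           stack$xll, stack$yll)
}

#' Validate a classification against labelled points
#'
#' Extracts the predicted class at each validation point and returns the
#' full accuracy report (overall/user's/producer's accuracy, Q, A, QADI).
#'
#' @param cm Predicted [classmap()].
#' @param samples Data frame with `row`, `col`, `class_code` (rows tagged
#'   `split == "validation"` are used if a `split` column is present).
#' @return An [accuracy_report()].
#' @export
validate_map <- function(cm, samples) {
  stopifnot(is_classmap(cm))
  s <- samples
  if (!is.null(s$split)) s <- s[s$split == "validation", , drop = FALSE]
  pred <- cm$codes[cbind(s$row, s$col)]
  keep <- !is.na(pred)
  conf <- build_confusion(s$class_code[keep], pred[keep], cm$legend)
  accuracy_report(conf)
}
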