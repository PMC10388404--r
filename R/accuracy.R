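#' Build a confusion matrix from paired labels
#'
#' Rows are the classified (map/user) classes, columns the reference
#' classes: `counts[i, j]` is the number of points mapped as class i whose
#' reference label is class j. Marginal totals are always recomputed from
#' the cells, never taken on trust from a source table.
#'
#' @param ref_labels,pred_labels Equal-length vectors of class labels
#'   (codes or names present in `legend`).
#' @param legend Data frame `code,name`, or a character vector of class
#'   names fixing the class order.
#' @return An object of class `confusion_matrix`: a list with the integer
#'   `counts` matrix (classified x reference), `labels`, and total `N`.
#' @examples
#' cm <- build_confusion(c("m", "m", "w"), c("m", "w", "w"), c("m", "w"))
#' cm$counts
#' @export
build_confusion <- function(ref_labels, pred_labels, legend) {
  if (length(ref_labels) != length(pred_labels))
    stop("reference and predicted label vectors must have equal length")
  if (length(ref_labels) == 0L) stop("empty label vectors")
  if (is.data.frame(legend)) {
    labels <- legend$name
    ref_labels <- relabel(ref_labels, legend)
    pred_labels <- relabel(pred_labels, legend)
  } else {
    labels <- as.character(legend)
    ref_labels <- as.character(ref_labels)
    pred_labels <- as.character(pred_labels)
  }
  for (v in list(ref_labels, pred_labels)) {
    bad <- setdiff(unique(v), labels)
    if (length(bad))
      stop("label not in legend: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(pred_labels, levels = labels),
                  factor(ref_labels, levels = labels))
  confusion_matrix(unclass(counts), labels)
}

#' @rdname build_confusion
#' @param counts k x k nonnegative count matrix (rows = classified).
#' @param labels Class names, recycled to row/column names.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(classified = labels, reference = labels)
  N <- sum(counts)
  if (N <= 0) stop("confusion matrix is empty (N = 0)")
  structure(list(counts = counts, labels = as.character(labels), N = N),
            class = "confusion_matrix")
}

relabel <- function(x, legend) {
  if (is.numeric(x)) {
    i <- match(x, legend$code)
    out <- legend$name[i]
    out[is.na(i)] <- as.character(x)[is.na(i)]
    out
  } else as.character(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> N =", x$N, "\n")
  print(x$counts)
  invisible(x)
}

#' Overall classification accuracy
#'
#' Percentage of correctly classified points: `100 * trace / N`.
#'
#' @param cm A [confusion_matrix()].
#' @return Overall accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  100 * sum(diag(cm$counts)) / cm$N
}

#' Per-class user's and producer's accuracy
#'
#' User's accuracy (commission view) is the diagonal over the row total;
#' producer's accuracy (omission view) is the diagonal over the column
#' total. Classes with a zero denominator are `NA`.
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with columns `class`, `users_accuracy`,
#'   `producers_accuracy` (percent).
#' @export
class_accuracies <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  d <- diag(cm$counts)
  rt <- rowSums(cm$counts); ct <- colSums(cm$counts)
  data.frame(class = cm$labels,
             users_accuracy = ifelse(rt > 0, 100 * d / rt, NA_real_),
             producers_accuracy = ifelse(ct > 0, 100 * d / ct, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantity and allocation disagreement
#'
#' Decomposes the total disagreement `D = N - trace` into quantity
#' disagreement `Q` — the mismatch between classified and reference class
#' totals, `Q = sum_g |row_g - col_g| / 2` — and allocation disagreement
#' `A = D - Q`, the disagreement attributable to spatial mislabelling at
#' matched totals.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(Q, A, D)`.
#' @export
disagreement <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  D <- cm$N - sum(diag(cm$counts))
  Q <- sum(abs(rowSums(cm$counts) - colSums(cm$counts))) / 2
  c(Q = Q, A = D - Q, D = D)
}

#' Quantity-allocation disagreement index (QADI)
#'
#' `QADI = sqrt((A/N)^2 + (Q/N)^2)`, a \[0, 1\] accuracy index combining
#' the quantity and allocation components of disagreement, with a five-step
#' confidence scale: QADI below 0.07 is "Very high confidence", 0.07-0.12
#' "High confidence", 0.12-0.20 "Moderate confidence", 0.20-0.30 "Low
#' confidence" and 0.30 or more "Very low confidence".
#'
#' @param cm A [confusion_matrix()].
#' @return A list with `qadi` and the `confidence` label.
#' @examples
#' cm <- confusion_matrix(diag(5, 2), c("a", "b"))
#' qadi(cm)   # 0, very high confidence
#' @export
qadi <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  qa <- disagreement(cm)
  val <- sqrt((qa[["A"]] / cm$N)^2 + (qa[["Q"]] / cm$N)^2)
  list(qadi = val, confidence = qadi_confidence(val))
}

#' @rdname qadi
#' @param value A QADI value in \[0, 1\].
#' @export
qadi_confidence <- function(value) {
  stopifnot(value >= 0)
  breaks <- c(0, 0.07, 0.12, 0.20, 0.30, 1)
  labels <- c("Very high confidence", "High confidence",
              "Moderate confidence", "Low confidence",
              "Very low confidence")
  labels[pmin(findInterval(value, breaks, rightmost.closed = TRUE), 5L)]
}

#' Full accuracy report
#'
#' Convenience wrapper assembling overall accuracy, per-class user's and
#' producer's accuracy, the quantity/allocation decomposition, QADI and its
#' confidence class in one object.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `accuracy_report`.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  qa <- disagreement(cm)
  qi <- qadi(cm)
  structure(list(
    N = cm$N,
    overall_accuracy = overall_accuracy(cm),
    class_accuracies = class_accuracies(cm),
    quantity_disagreement = qa[["Q"]],
    allocation_disagreement = qa[["A"]],
    total_disagreement = qa[["D"]],
    qadi = qi$qadi, confidence = qi$confidence),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%% (N = %d)\n", x$overall_accuracy,
              x$N))
  cat(sprintf("Disagreement: Q = %g, A = %g, D = %g\n",
              x$quantity_disagreement, x$allocation_disagreement,
              x$total_disagreement))
  cat(sprintf("QADI = %.5f (%s)\n", x$qadi, x$confidence))
  print(x$class_accuracies, digits = 4)
  invisible(x)
}
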