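#' Dice and IoU overlap between two binary masks
#'
#' Dice = 2|A intersect B| / (|A| + |B|) and IoU = |A intersect B| / |A union B|.
#' When both masks are empty there is nothing to disagree about and both
#' scores are 1 by convention, so phantom sweeps with absent structures do not
#' crash. The two scores always satisfy dice = 2 iou / (1 + iou).
#'
#' @param pred,truth Arrays/matrices of the same shape; compared as
#'   `== label` when `label` is given, else as logical.
#' @param label Optional label value selecting the foreground class.
#' @return A `vm_overlap`: list with `dice`, `iou`, `region_label`.
#' @export
dice_iou <- function(pred, truth, label = NULL) {
  if (inherits(pred, "vm_volume")) pred <- pred$data
  if (inherits(truth, "vm_volume")) truth <- truth$data
  if (inherits(pred, "vm_label_slice")) pred <- pred$data
  if (inherits(truth, "vm_label_slice")) truth <- truth$data
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  if (!is.null(label)) { pred <- pred == label; truth <- truth == label }
  pred <- as.logical(pred); truth <- as.logical(truth)
  inter <- sum(pred & truth)
  union <- sum(pred | truth)
  sizes <- sum(pred) + sum(truth)
  if (union == 0) {
    dice <- 1; iou <- 1
  } else {
    dice <- 2 * inter / sizes
    iou <- inter / union
  }
  structure(list(dice = dice, iou = iou,
                 region_label = if (is.null(label)) NA_integer_ else as.integer(label)),
            class = "vm_overlap")
}

#' @export
print.vm_overlap <- function(x, ...) {
  cat(sprintf("<fetalvm overlap> dice %.4f, iou %.4f\n", x$dice, x$iou))
  invisible(x)
}

#' Multi-class classification report
#'
#' Confusion matrix (rows = true class, columns = predicted class) plus
#' per-class precision, recall and F1, overall accuracy and macro F1 (the
#' unweighted mean of per-class F1, informative under class imbalance).
#' Precision is 0 (flagged via `precision_defined = FALSE`) when a class is
#' never predicted, keeping macro averages finite on small cohorts; the same
#' convention applies to recall for classes with no support.
#'
#' @param true_labels,pred_labels Equal-length vectors of class labels.
#' @param classes Class set and its order (default [severity_classes()]).
#' @return A `vm_class_metrics`: list with `confusion` (matrix), `per_class`
#'   (tibble), `accuracy`, `macro_f1`, `n`.
#' @export
#' @examples
#' truth <- c("Normal", "Normal", "Mild", "Severe")
#' pred  <- c("Normal", "Mild",  "Mild", "Severe")
#' classification_report(truth, pred)
classification_report <- function(true_labels, pred_labels,
                                  classes = severity_classes()) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  unknown <- setdiff(unique(c(true_labels, pred_labels)), classes)
  if (length(unknown))
    stop("unknown label value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tf <- factor(true_labels, levels = classes)
  pf <- factor(pred_labels, levels = classes)
  confusion <- table(true = tf, predicted = pf)
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  metrics_from_confusion(confusion)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the same report as [classification_report()] directly from counts
#' (rows = true class, columns = predicted class), e.g. a published confusion
#' matrix.
#'
#' @param confusion Square count matrix with identical row/column class names.
#' @return A `vm_class_metrics`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  if (any(confusion < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  classes <- rownames(confusion)
  if (is.null(classes)) {
    classes <- paste0("class", seq_len(nrow(confusion)))
    dimnames(confusion) <- list(true = classes, predicted = classes)
  }
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  true_tot <- rowSums(confusion)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    class = classes,
    support = as.integer(true_tot),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    precision_defined = pred_tot > 0,
    recall_defined = true_tot > 0)
  total <- sum(confusion)
  structure(list(confusion = confusion,
                 per_class = per_class,
                 accuracy = if (total > 0) sum(tp) / total else NA_real_,
                 macro_f1 = mean(f1),
                 n = as.integer(total)),
            class = "vm_class_metrics")
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return F1 score (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' @export
print.vm_class_metrics <- function(x, ...) {
  cat(sprintf("<fetalvm classification metrics> n = %d, accuracy %.3f, macro F1 %.3f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$confusion)
  print(as.data.frame(x$per_class[, c("class", "support", "precision",
                                      "recall", "f1")]), digits = 3)
  invisible(x)
}

#' Tidy per-class metrics
#'
#' @param x A `vm_class_metrics`.
#' @param ... Unused.
#' @return The per-class tibble (class, support, precision, recall, f1, flags).
#' @export
tidy.vm_class_metrics <- function(x, ...) x$per_class

#' One-row summary of a classification report
#'
#' @param x A `vm_class_metrics`.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `macro_f1`.
#' @export
glance.vm_class_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_f1 = x$macro_f1)
}
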