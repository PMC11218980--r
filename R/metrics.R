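#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs; rows are the true class.
#'
#' @param truth,pred Integer 1-based class indices of equal length.
#' @param n_classes Number of classes (default 4).
#' @param class_levels Dimension names.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 4L,
                             class_levels = tumor_classes()) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = class_levels[seq_len(n_classes)],
                               predicted = class_levels[seq_len(n_classes)]))
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Overall accuracy
#'
#' Correct predictions over all evaluated samples, as a percentage.
#'
#' @param cm A [confusion_matrix()].
#' @return Percent in `[0, 100]`.
#' @export
overall_accuracy <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' Per-class accuracy
#'
#' `100 * correct_in_class / total_in_class` for one class, or for all
#' classes when `class_id` is `NULL`. A class absent from the test set is
#' reported as `NA` (undefined), never as zero.
#'
#' @param cm A [confusion_matrix()].
#' @param class_id 1-based class index, or `NULL` for all.
#' @return Percent(s).
#' @export
per_class_accuracy <- function(cm, class_id = NULL) {
  totals <- rowSums(cm)
  acc <- ifelse(totals > 0, 100 * diag(cm) / totals, NA_real_)
  if (is.null(class_id)) acc else acc[[class_id]]
}

#' One-vs-rest precision, recall and F1
#'
#' For a class: `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1` their harmonic mean, all in percent. Zero denominators yield `NA`
#' with a warning, and `NA` classes are excluded from the macro means.
#'
#' @param cm A [confusion_matrix()].
#' @param class_id 1-based class index, or `NULL` for a per-class tibble
#'   plus macro averages.
#' @return For one class, a named vector `(precision, recall, f1)`; for
#'   all, a tibble with a `"macro"` summary row.
#' @export
precision_recall_f1 <- function(cm, class_id = NULL) {
  one <- function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    f <- f1_score(p, r)
    if (anyNA(c(p, r))) {
      warning("undefined precision/recall for class ", rownames(cm)[i],
              " (zero denominator); excluded from macro averages",
              call. = FALSE)
    }
    c(precision = p, recall = r, f1 = f)
  }
  if (!is.null(class_id)) return(one(class_id))
  per <- t(vapply(seq_len(nrow(cm)), one, numeric(3)))
  out <- tibble::tibble(class = rownames(cm),
                        precision = per[, 1], recall = per[, 2], f1 = per[, 3])
  dplyr::bind_rows(out,
                   tibble::tibble(class = "macro",
                                  precision = mean(per[, 1], na.rm = TRUE),
                                  recall = mean(per[, 2], na.rm = TRUE),
                                  f1 = mean(per[, 3], na.rm = TRUE)))
}

#' F1 from precision and recall percentages
#'
#' `2 P R / (P + R)`; the harmonic mean, in percent.
#'
#' @param precision,recall Percentages.
#' @return Percent, or `NA` if either input is `NA`.
#' @export
f1_score <- function(precision, recall) {
  if (anyNA(c(precision, recall))) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Precision-recall curve for one class
#'
#' Sweeps every distinct score threshold (one-vs-rest) and records the
#' precision and recall attained; recall is non-decreasing along the sweep.
#'
#' @param scores Numeric matrix `n x n_classes` of class scores (or a
#'   vector of scores for `class_id` itself).
#' @param labels 1-based true class indices.
#' @param class_id Class under evaluation.
#' @return A tibble of class `pr_curve` with columns `threshold`, `recall`,
#'   `precision`.
#' @export
pr_curve <- function(scores, labels, class_id) {
  s <- if (is.matrix(scores)) scores[, class_id] else scores
  pos <- labels == class_id
  if (all(pos) || !any(pos)) {
    stop("PR curve needs both positive and negative samples for class ",
         class_id, call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each distinct score
  out <- tibble::tibble(threshold = s[keep],
                        recall = tp[keep] / sum(pos),
                        precision = tp[keep] / (tp[keep] + fp[keep]))
  class(out) <- c("pr_curve", class(out))
  out
}

#' Normal-approximation 95% confidence interval for an accuracy
#'
#' `acc +- 1.96 * sqrt(acc * (100 - acc) / n)`, clamped to `[0, 100]`.
#'
#' @param accuracy Accuracy in percent.
#' @param n Number of evaluated samples (> 0; the approximation is meant
#'   for `n >= 30`).
#' @return Named vector `(low, high)` in percent.
#' @export
accuracy_ci95 <- function(accuracy, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n < 30) warning("normal approximation is poor for n < 30", call. = FALSE)
  half <- 1.96 * sqrt(accuracy * (100 - accuracy) / n)
  c(low = max(0, accuracy - half), high = min(100, accuracy + half))
}

#' Full metric report
#'
#' Combines overall accuracy and its 95% interval, per-class accuracy and
#' one-vs-rest precision/recall/F1 (with macro averages) into one tidy
#' table.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with columns `class`, `n`, `accuracy`, `precision`,
#'   `recall`, `f1`, `ci_low`, `ci_high`; per-class rows, then a
#'   `"overall"` row (accuracy + CI) and a `"macro"` row.
#' @export
metric_report <- function(cm) {
  prf <- precision_recall_f1(cm)
  acc <- overall_accuracy(cm)
  ci <- accuracy_ci95(acc, sum(cm))
  per <- prf |>
    dplyr::filter(.data$class != "macro") |>
    dplyr::mutate(n = unname(rowSums(unclass(cm))),
                  accuracy = unname(per_class_accuracy(cm)),
                  ci_low = NA_real_, ci_high = NA_real_)
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "overall", n = sum(cm), accuracy = acc,
                   precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                   ci_low = ci[["low"]], ci_high = ci[["high"]]),
    prf |> dplyr::filter(.data$class == "macro") |>
      dplyr::mutate(n = sum(cm), accuracy = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)) |>
    dplyr::select(dplyr::all_of(c("class", "n", "accuracy", "precision",
                                  "recall", "f1", "ci_low", "ci_high")))
}
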