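#' Evaluate a classifier's predictions
#'
#' Computes overall accuracy, per-class recall (TP over class support),
#' macro recall (unweighted mean of per-class recalls — the single-number
#' summary that is sensitive to minority-class performance) and the
#' confusion matrix. A class present in the class set but absent from
#' `truth` has undefined recall and is excluded from the macro average
#' with a warning.
#'
#' @param pred,truth Equal-length label vectors.
#' @return An `eval_report`: `accuracy`, `recall` (named per class),
#'   `macro_recall`, `confusion` (truth in rows), `n`.
#' @examples
#' evaluate_classification(c("a", "a", "b"), c("a", "b", "b"))
#' @export
evaluate_classification <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  classes <- sort(unique(c(pred, truth)))
  cm <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  support <- rowSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
  names(recall) <- classes
  if (any(support == 0))
    warning("class(es) absent from truth, excluded from macro recall: ",
            paste(classes[support == 0], collapse = ", "))
  structure(list(accuracy = sum(diag(cm)) / length(truth),
                 recall = recall,
                 macro_recall = mean(recall, na.rm = TRUE),
                 confusion = cm, n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n,
      " accuracy =", sprintf("%.4f", x$accuracy),
      " macro recall =", sprintf("%.4f", x$macro_recall), "\n")
  cat("per-class recall:\n")
  print(round(x$recall, 4))
  cat("confusion (truth in rows):\n")
  print(x$confusion)
  invisible(x)
}

#' Relative improvement in percent
#'
#' `100 * (new - baseline) / baseline`: the conventional way of reporting
#' how much one model's metric improves on another's.
#'
#' @param new New value.
#' @param baseline Reference value (> 0).
#' @return Percentage (positive when `new` exceeds `baseline`).
#' @examples
#' relative_improvement(0.8913, 0.7687) # about 15.95
#' @export
relative_improvement <- function(new, baseline) {
  if (!is.numeric(baseline) || baseline <= 0)
    stop("baseline must be positive")
  100 * (new - baseline) / baseline
}

#' Write an evaluation report as delimited text
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_eval_report <- function(report, path) {
  lines <- c(
    sprintf("metric,class,value"),
    sprintf("accuracy,,%.10g", report$accuracy),
    sprintf("macro_recall,,%.10g", report$macro_recall),
    sprintf("recall,%s,%.10g", names(report$recall), report$recall),
    sprintf("n,,%d", report$n))
  writeLines(lines, path)
  invisible(path)
}
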