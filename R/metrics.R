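#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Ordered class labels; every label must belong to it.
#' @return Integer matrix of class `grade_confusion` with the layout
#'   Actual \\ Predicted.
#' @export
confusion <- function(actual, predicted, classes = GRADE_LEVELS) {
  if (length(actual) != length(predicted))
    stop("actual and predicted lengths differ")
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  out <- matrix(as.integer(m), length(classes), length(classes),
                dimnames = list(Actual = classes, Predicted = classes))
  structure(out, class = c("grade_confusion", class(out)))
}

#' @export
print.grade_confusion <- function(x, ...) {
  cat("Actual \\ Predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and support-weighted classification metrics
#'
#' Precision_i = TP_i / (TP_i + FP_i), Recall_i = TP_i / (TP_i + FN_i),
#' F1_i = 2 P_i R_i / (P_i + R_i); overall metrics are the
#' support-weighted means sum(n_i m_i) / sum(n_i). Vanishing
#' denominators yield 0 with the class flagged in `zero_division`.
#' Values are proportions; multiply by 100 for the percent convention.
#'
#' @param cm A [confusion()] matrix.
#' @return List with `per_class` (data.frame: class, precision, recall,
#'   f1, support), `overall` (named vector), `zero_division` (character).
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "grade_confusion"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  n <- rowSums(cm)
  flagged <- character()
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / den, 0)
    flagged <<- union(flagged, rownames(cm)[den == 0])
    out
  }
  P <- safe_div(tp, tp + fp)
  R <- safe_div(tp, tp + fn)
  F1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  flagged <- union(flagged, rownames(cm)[P + R == 0])
  w <- if (sum(n) > 0) n / sum(n) else rep(0, length(n))
  list(per_class = data.frame(class = rownames(cm), precision = as.numeric(P),
                              recall = as.numeric(R), f1 = as.numeric(F1),
                              support = as.integer(n)),
       overall = c(precision = sum(w * P), recall = sum(w * R),
                   f1 = sum(w * F1)),
       zero_division = flagged)
}

#' Reconstruct label pairs from a confusion matrix
#'
#' Expands the cell counts back into (actual, predicted) label vectors —
#' handy for recomputing metrics from published confusion tables.
#'
#' @param counts Square matrix of counts, rows = actual.
#' @param classes Class labels.
#' @return List with `actual` and `predicted` character vectors.
#' @export
labels_from_confusion <- function(counts, classes = GRADE_LEVELS) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(classes), ncol(counts) == length(classes))
  actual <- rep(rep(classes, times = rowSums(counts)))
  predicted <- unlist(lapply(seq_along(classes), function(i)
    rep(classes, times = counts[i, ])))
  list(actual = actual, predicted = predicted)
}
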