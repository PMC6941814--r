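#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank handling of tied scores; a
#' constant score therefore gives 0.5.
#'
#' @param labels Binary vector.
#' @param scores Numeric scores, larger = more positive.
#' @return AU-ROC in `[0, 1]`, or `NA` (with a warning) when a class has
#'   no positives or no negatives.
#' @export
auroc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AU-ROC undefined: class has no positives or no negatives")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision step integral: `sum (R_i - R_{i-1}) * P_i` over
#' distinct score thresholds in decreasing order.
#'
#' @inheritParams auroc
#' @return AU-PR in `[0, 1]`, or `NA` when there are no positives.
#' @export
aupr <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0L) {
    warning("AU-PR undefined: class has no positives")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each threshold
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  rec <- tp / n1
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a trained CNN on a dataset split
#'
#' Computes per-class AU-ROC and AU-PR from the sigmoid outputs against
#' the binary labels, plus their unweighted means. Classes without both
#' a positive and a negative example are reported as `NA` and excluded
#' from the means with a warning.
#'
#' @param model A trained `cnn_model`.
#' @param dataset A `synthetic_dataset`.
#' @param split `"test"`, `"validation"` or `"train"`.
#' @return A `cnn_evaluation`: tibble with columns `class`, `auroc`,
#'   `aupr`, and attributes `mean_auroc`, `mean_aupr`.
#' @export
evaluate_cnn <- function(model, dataset, split = "test") {
  idx <- dataset$split[[split]]
  if (!length(idx)) stop("split '", split, "' is empty")
  probs <- predict(model, dataset$x[, , idx, drop = FALSE])
  y <- dataset$y[idx, , drop = FALSE]
  per <- tibble::tibble(
    class = colnames(y),
    auroc = vapply(seq_len(ncol(y)),
                   function(j) auroc(y[, j], probs[, j]), numeric(1)),
    aupr = vapply(seq_len(ncol(y)),
                  function(j) aupr(y[, j], probs[, j]), numeric(1)))
  structure(per, class = c("cnn_evaluation", class(per)),
            mean_auroc = mean(per$auroc, na.rm = TRUE),
            mean_aupr = mean(per$aupr, na.rm = TRUE),
            split = split)
}

#' @export
print.cnn_evaluation <- function(x, ...) {
  NextMethod()
  cat(sprintf("# mean AU-ROC %.4f, mean AU-PR %.4f (%s split)\n",
              attr(x, "mean_auroc"), attr(x, "mean_aupr"),
              attr(x, "split")))
  invisible(x)
}
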