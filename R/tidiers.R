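#' Tidy the training history of a CNN
#'
#' @param x A trained `cnn_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  x$history
}

#' One-row summary of a CNN
#'
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @return Tibble with the variant name, parameter count, best epoch and
#'   best validation loss.
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(variant = x$spec$name, n_parameters = n_parameters(x),
                 trained = x$trained, best_epoch = x$best_epoch,
                 best_val_loss = if (is.null(x$history)) NA_real_
                                 else min(x$history$val_loss))
}

#' Per-filter rows of a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return The per-filter results tibble.
#' @export
tidy.match_report <- function(x, ...) x$results

#' One-row summary of a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return Tibble with filter count and the two match fractions.
#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(n_filters = x$n_filters, frac_any = x$frac_any,
                 frac_relevant = x$frac_relevant, e_cutoff = x$e_cutoff)
}

#' One-row summary of a CNN evaluation
#'
#' @param x A `cnn_evaluation` from [evaluate_cnn()].
#' @param ... Unused.
#' @return Tibble with macro-averaged AU-ROC and AU-PR.
#' @export
glance.cnn_evaluation <- function(x, ...) {
  tibble::tibble(split = attr(x, "split"),
                 mean_auroc = attr(x, "mean_auroc"),
                 mean_aupr = attr(x, "mean_aupr"))
}
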