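# End-to-end orchestration: train a variant, evaluate it, interpret its
# filters, match them against ground truth, and tabulate the results.

# Which layers are interpreted for each variant: always layer 1; deeper
# layers only where no pooling precedes them.
interpret_layers <- function(variant) {
  if (startsWith(variant, "CNN-1-1-100")) return(1:3)
  if (variant == "CNN-1" || startsWith(variant, "CNN-1(")) return(1:2)
  1L
}

#' Train and fully analyse one CNN variant
#'
#' Builds the variant, trains it, computes test AU-ROC/AU-PR, distills
#' filter PPMs for every interpretable layer (layer 1 always; deeper
#' layers when no pooling precedes them, as for CNN-1 and CNN-1-1-100)
#' and matches them against the ground-truth pool.
#'
#' @param variant Variant name for [cnn_variant()].
#' @param dataset A `synthetic_dataset`.
#' @param pool The ground-truth [motif_pool()] used for matching.
#' @param epochs,batch_size,learning_rate Training protocol.
#' @param seed Seed for initialization, shuffling and the permutation
#'   null.
#' @param n_filters1 Optional first-layer filter-count override.
#' @param threshold_frac Activation cutoff for [build_ppm()].
#' @param e_cutoff,n_shuffle,min_overlap,n_database Matching parameters
#'   (see [match_report()]); `n_database = 519` reproduces the
#'   multiple-testing burden of a JASPAR-2016-scale database search.
#' @param layers Layers to interpret; default per variant.
#' @param keep Also return the trained model, PPMs and reports.
#' @return A tibble with one row per interpreted layer (columns:
#'   `variant`, `layer`, `n_filters`, `mean_auroc`, `mean_aupr`,
#'   `frac_any`, `frac_relevant`, `n_empty`, `best_epoch`). With
#'   `keep = TRUE`, a list with `summary`, `model`, `evaluation`,
#'   `ppms`, `reports`.
#' @export
run_experiment <- function(variant, dataset, pool = default_motif_pool(),
                           epochs = 30L, batch_size = 100L,
                           learning_rate = 3e-4, seed = 1L,
                           n_filters1 = NULL, threshold_frac = 0.7,
                           e_cutoff = 0.1, n_shuffle = 1000L,
                           min_overlap = 4L, n_database = NULL,
                           layers = NULL, keep = FALSE) {
  spec <- cnn_variant(variant, n_filters1 = n_filters1)
  model <- build_cnn(spec, input_length = dataset$length, seed = seed)
  model <- train_cnn(model, dataset, epochs = epochs,
                     batch_size = batch_size,
                     learning_rate = learning_rate, seed = seed)
  ev <- evaluate_cnn(model, dataset, "test")
  if (is.null(layers)) layers <- interpret_layers(spec$name)
  xtest <- dataset$x[, , dataset$split$test, drop = FALSE]
  ppms <- list()
  reports <- list()
  rows <- purrr::map(layers, function(ly) {
    sc <- scan_activations(model, xtest, layer = ly)
    pp <- build_ppm(sc, xtest, threshold_frac = threshold_frac)
    rep <- match_report(pp, pool, e_cutoff = e_cutoff,
                        n_shuffle = n_shuffle, min_overlap = min_overlap,
                        seed = seed + ly, n_database = n_database)
    ppms[[as.character(ly)]] <<- pp
    reports[[as.character(ly)]] <<- rep
    tibble::tibble(variant = spec$name, layer = ly,
                   n_filters = rep$n_filters,
                   mean_auroc = attr(ev, "mean_auroc"),
                   mean_aupr = attr(ev, "mean_aupr"),
                   frac_any = rep$frac_any,
                   frac_relevant = rep$frac_relevant,
                   n_empty = sum(vapply(pp, function(p) p$empty,
                                        logical(1))),
                   best_epoch = model$best_epoch)
  })
  summary <- dplyr::bind_rows(rows)
  if (!keep) return(summary)
  list(summary = summary, model = model, evaluation = ev, ppms = ppms,
       reports = reports)
}

#' Run an architecture sweep
#'
#' Trains every requested variant for `n_trials` independent trials on
#' one shared dataset (all variants see the same data; trial seeds vary
#' only initialization, shuffling, dropout and the permutation null) and
#' collects a results table. Per-(variant, trial) failures are recorded
#' in an `error` column without aborting the sweep.
#'
#' @param variants Character vector of variant names.
#' @param dataset A `synthetic_dataset` shared by all runs.
#' @param n_trials Independent trials per variant.
#' @param train_seeds Integer seeds, one per trial.
#' @param output_dir Optional directory for artifacts: per-run training
#'   histories, PPM MEME files, the results table and a manifest.
#' @param verbose Print progress.
#' @inheritParams run_experiment
#' @return A `results_table` tibble with one row per
#'   (variant, trial, layer).
#' @export
run_sweep <- function(variants, dataset, pool = default_motif_pool(),
                      n_trials = 1L, train_seeds = seq_len(n_trials),
                      epochs = 30L, batch_size = 100L,
                      learning_rate = 3e-4, threshold_frac = 0.7,
                      e_cutoff = 0.1, n_shuffle = 1000L,
                      n_database = NULL, output_dir = NULL,
                      verbose = FALSE) {
  stopifnot(length(train_seeds) == n_trials)
  if (!is.null(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- tidyr::expand_grid(variant = variants,
                             trial = seq_len(n_trials))
  rows <- purrr::pmap(runs, function(variant, trial) {
    sd <- train_seeds[trial]
    if (verbose) message("== ", variant, " trial ", trial, " (seed ", sd,
                         ") ==")
    res <- tryCatch({
      r <- run_experiment(variant, dataset, pool, epochs = epochs,
                          batch_size = batch_size,
                          learning_rate = learning_rate, seed = sd,
                          threshold_frac = threshold_frac,
                          e_cutoff = e_cutoff, n_shuffle = n_shuffle,
                          n_database = n_database,
                          keep = !is.null(output_dir))
      if (!is.null(output_dir)) {
        tag <- sprintf("%s_trial%d", gsub("[^A-Za-z0-9._-]", "_", variant),
                       trial)
        utils::write.csv(r$model$history,
                         file.path(output_dir, paste0(tag, "_history.csv")),
                         row.names = FALSE)
        for (ly in names(r$ppms)) {
          if (any(!vapply(r$ppms[[ly]], function(p) p$empty, logical(1))))
            write_meme(r$ppms[[ly]],
                       file.path(output_dir,
                                 paste0(tag, "_layer", ly, "_ppms.meme")))
        }
        r <- r$summary
      }
      r$trial <- trial
      r$seed <- sd
      r$error <- NA_character_
      r
    }, error = function(e) {
      tibble::tibble(variant = variant, layer = NA_integer_,
                     n_filters = NA_integer_, mean_auroc = NA_real_,
                     mean_aupr = NA_real_, frac_any = NA_real_,
                     frac_relevant = NA_real_, n_empty = NA_integer_,
                     best_epoch = NA_integer_, trial = trial, seed = sd,
                     error = conditionMessage(e))
    })
    res
  })
  tbl <- dplyr::bind_rows(rows)
  class(tbl) <- c("results_table", class(tbl))
  if (!is.null(output_dir)) {
    utils::write.table(tbl, file.path(output_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(variants = variants, n_trials = n_trials,
           train_seeds = train_seeds, epochs = epochs,
           batch_size = batch_size, learning_rate = learning_rate,
           threshold_frac = threshold_frac, e_cutoff = e_cutoff,
           n_shuffle = n_shuffle, data_seed = dataset$seed,
           n_sequences = dim(dataset$x)[3], timestamp = as.character(Sys.time())),
      file.path(output_dir, "manifest.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  tbl
}

#' Sweep over the number of first-layer filters
#'
#' Repeats the base variant (CNN-25 by default) with the first
#' convolutional layer widened to each requested filter count.
#'
#' @param counts Integer vector of first-layer filter counts.
#' @param base_variant Variant whose geometry is kept fixed.
#' @inheritParams run_sweep
#' @return A `results_table` tibble.
#' @export
filter_count_sweep <- function(counts, dataset,
                               base_variant = "CNN-25", ...) {
  run_sweep(sprintf("%s(%d)", base_variant, counts), dataset, ...)
}

#' Aggregate a sweep into per-variant means and standard deviations
#'
#' @param tbl A `results_table` from [run_sweep()].
#' @return Tibble with one row per (variant, layer) and `mean`/`sd`
#'   columns for AU-ROC, AU-PR and the match fractions.
#' @export
summarise_sweep <- function(tbl) {
  tbl |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$variant, .data$layer) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      dplyr::across(c("mean_auroc", "mean_aupr", "frac_any",
                      "frac_relevant"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop")
}
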