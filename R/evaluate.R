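# Evaluation of a generated dataset: independent retraining, per-class
# score histograms with an overlap coefficient, and the exact marginal
# conservation audit.

#' Per-class score histograms and overlap coefficient
#'
#' Each row is reduced to a single score -- the sum of its feature columns
#' (normalized age included by default) -- and the two outcome classes are
#' binned on shared equal-width edges spanning the pooled score range
#' (100 bins by default). The overlap coefficient is the summed bin-wise
#' minimum of the two normalized histograms: 1 for identical
#' distributions, 0 for perfectly separated classes.
#'
#' @param data A cohort tibble with feature columns and `label`.
#' @param bins Number of equal-width bins, default 100.
#' @param score_columns Columns summed into the score; defaults to all
#'   eight feature columns.
#' @return An object of class `score_histograms`: `bin_edges` (length
#'   `bins + 1`), integer `class0_counts` and `class1_counts`, and
#'   `overlap_coefficient` (`NA` when only one class is present).
#' @export
class_score_histograms <- function(data, bins = 100, score_columns = NULL) {
  assert_cohort(data)
  score_columns <- score_columns %||% feature_columns()
  stopifnot(is_count(bins), bins >= 1)
  score <- rowSums(as.matrix(data[, score_columns, drop = FALSE]))
  lab <- data$label > 0.5
  rng <- range(score)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  bin_of <- function(x) {
    if (length(x) == 0) return(integer(bins))
    tabulate(findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE),
             nbins = bins)
  }
  c0 <- bin_of(score[!lab])
  c1 <- bin_of(score[lab])
  n0 <- sum(c0); n1 <- sum(c1)
  overlap <- if (n0 > 0 && n1 > 0) sum(pmin(c0 / n0, c1 / n1)) else NA_real_
  structure(
    list(bin_edges = edges, class0_counts = c0, class1_counts = c1,
         overlap_coefficient = overlap, n_class0 = n0, n_class1 = n1),
    class = "score_histograms"
  )
}

#' @export
print.score_histograms <- function(x, ...) {
  cat("<score_histograms>", length(x$class0_counts), "bins;",
      x$n_class0, "healthy /", x$n_class1, "diabetic rows\n")
  cat("overlap coefficient:",
      if (is.na(x$overlap_coefficient)) "undefined (single class)"
      else sprintf("%.4f", x$overlap_coefficient), "\n")
  invisible(x)
}

#' Audit a dataset's marginal counts against its recorded targets
#'
#' For every (age group, outcome) subgroup and binary feature column,
#' compares the observed ones-count with the target recorded when the
#' table was generated (or balanced). The shuffle operators preserve
#' these counts exactly, so any nonzero difference flags corruption.
#'
#' @param data A cohort tibble with subgroup provenance.
#' @param targets Target marginals as produced by [cohort_marginals()];
#'   defaults to the table's `targets` attribute.
#' @return A tibble with one row per (subgroup, column):
#'   `target_ones`, `observed_ones`, `difference`; attribute `passed` is
#'   `TRUE` iff every difference is zero. See [audit_passed()].
#' @export
audit_statistics <- function(data, targets = NULL) {
  assert_cohort(data, need_provenance = TRUE)
  targets <- targets %||% attr(data, "targets")
  if (is.null(targets)) {
    stop("no marginal targets: the table carries no `targets` attribute ",
         "and none were supplied", call. = FALSE)
  }
  observed <- cohort_marginals(data)
  report <- dplyr::full_join(
    dplyr::rename(targets, target_n = "n", target_ones = "ones"),
    dplyr::rename(observed, observed_n = "n", observed_ones = "ones"),
    by = c(".age_group", ".outcome", "column")
  ) |>
    dplyr::mutate(difference = abs(.data$observed_ones - .data$target_ones))
  passed <- all(!is.na(report$difference)) && all(report$difference == 0) &&
    all(report$target_n == report$observed_n)
  attr(report, "passed") <- passed
  class(report) <- unique(c("cohort_audit", class(report)))
  report
}

#' Did a conservation audit pass?
#'
#' @param audit Result of [audit_statistics()].
#' @return `TRUE` iff every marginal difference is zero.
#' @export
audit_passed <- function(audit) isTRUE(attr(audit, "passed"))

#' Retrain the independent evaluation network on a dataset
#'
#' Judges a generated dataset the way its consumers would use it: the
#' deeper dropout network from [build_eval_network()] is trained from
#' scratch on an 8:2 split (random state 46 by default) and scored on the
#' held-out test rows.
#'
#' @param data A cohort tibble (typically the loop's best snapshot).
#' @param epochs Training epochs (default 100).
#' @param seed Split seed, default 46; the network seed is derived from it.
#' @param val_fraction Validation share of the training split.
#' @param lr,batch_size Training hyperparameters.
#' @return An `mlp_fit` with an extra `test_accuracy` field (accuracy on
#'   the held-out split after the final epoch).
#' @export
evaluate_best <- function(data, epochs = 100, seed = 46, val_fraction = 0.1,
                          lr = 1e-3, batch_size = 256) {
  assert_cohort(data)
  parts <- split_dataset(data, ratio = 0.8, seed = seed,
                         val_fraction = val_fraction)
  fit <- train_network(build_eval_network(), parts$train, parts$val,
                       epochs = epochs, seed = derive_seed(seed, 97),
                       lr = lr, batch_size = batch_size)
  fit$test_accuracy <- accuracy(fit, parts$test)
  fit$split_seed <- seed
  fit
}
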