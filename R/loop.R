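# The shuffle-train generation loop: per cycle, every subgroup is window-
# shuffled with shared parameters, the combined table is split 8:2 and a
# fresh loop classifier is trained for five epochs; its test accuracy
# drives the controller that sets the next window, and the dataset with the
# best test accuracy across cycles is the product.

#' Split a cohort into training, validation and test sets
#'
#' Rows are permuted under `seed` and split `ratio` : `1 - ratio` into
#' training and test (80:20 by default, within one row); a `val_fraction`
#' share of the training rows is carved out for per-epoch validation
#' tracking.
#'
#' @param data A cohort tibble.
#' @param ratio Training share, default 0.8.
#' @param seed Integer seed, default 46.
#' @param val_fraction Fraction of the training split held out for
#'   validation (default 0.1; 0 disables it).
#' @return Named list of tibbles `train`, `val`, `test` (a partition of the
#'   input rows).
#' @export
split_dataset <- function(data, ratio = 0.8, seed = 46, val_fraction = 0.1) {
  n <- nrow(data)
  if (n == 0) stop("cannot split an empty dataset", call. = FALSE)
  perm <- with_seed_(seed, sample.int(n))
  n_train <- round(ratio * n)
  train_idx <- perm[seq_len(n_train)]
  test_idx <- if (n_train < n) perm[(n_train + 1L):n] else integer(0)
  n_val <- round(val_fraction * n_train)
  val_idx <- train_idx[seq_len(n_val)]
  train_idx <- if (n_val < n_train) train_idx[(n_val + 1L):n_train] else integer(0)
  list(train = data[train_idx, ],
       val = data[val_idx, ],
       test = data[test_idx, ])
}

#' Pick the best cycle record
#'
#' The record with the highest test accuracy; ties go to the earliest
#' cycle. Invariant under reordering of the records.
#'
#' @param records A tibble of cycle records with `cycle` and
#'   `test_accuracy` columns.
#' @return The selected one-row tibble.
#' @export
select_best <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no cycle records to select from", call. = FALSE)
  }
  records <- records[order(records$cycle), ]
  records[which.max(records$test_accuracy), ]
}

#' Run the shuffle-train generation loop
#'
#' Executes the full pipeline: primary generation from the summary
#' statistics, class balancing by duplication, the one-time
#' Fisher-Yates-plus-mirror randomization of every subgroup, and then up
#' to `cycles` iterations of \{window-shuffle every subgroup with shared
#' parameters; combine; split 8:2; train a fresh loop classifier for
#' `epochs_per_cycle` epochs; evaluate test accuracy; update the window
#' fraction `P` through the Adam-like controller; advance the window start
#' `B`\}. The dataset snapshot with the highest test accuracy is returned.
#'
#' Marginal conservation holds end to end: every snapshot carries exactly
#' the per-subgroup column counts of the balanced primary database.
#'
#' @param config A [survey_config()].
#' @param cycles Maximum number of shuffle-train cycles (default 100).
#' @param epochs_per_cycle Training epochs per cycle (default 5).
#' @param P,B,b_increment Initial window parameters (defaults 0.1, 0, 0.12).
#' @param convention Controller sign convention, see [optimizer_state()].
#' @param placement Compensation placement of the main shuffle, see
#'   [rebalance_column()].
#' @param target_accuracy Optional early stop: end the loop once test
#'   accuracy reaches this value.
#' @param fixed_split Reuse the same 8:2 split every cycle instead of
#'   redrawing it with a cycle-derived seed.
#' @param reinit_network Re-initialize the loop classifier's weights at
#'   the start of every cycle (default); with `FALSE` one network is
#'   trained continuously across cycles, 5 epochs at a time, and
#'   `fixed_split = TRUE` is forced so held-out rows stay held out.
#' @param val_fraction Validation share of the training split.
#' @param lr,batch_size Training hyperparameters of the loop classifier.
#' @param snapshot_dir Optional directory; when given, every cycle's
#'   dataset is exported as `cycle_<k>.csv` (with provenance sidecar) and
#'   the cycle log as `cycles.jsonl`.
#' @param seed Optional integer overriding every configured seed
#'   (generation, shuffle, split, network streams are derived from it).
#' @param verbose Print a line per cycle.
#' @return An object of class `shuffle_loop`: `best_dataset` (cohort
#'   tibble), `best_cycle`, `records` (one row per cycle: P, B, train/val/
#'   test accuracy, snapshot path), `trace` (controller states) and the
#'   `config` used.
#' @export
run_generation_loop <- function(config, cycles = 100, epochs_per_cycle = 5,
                                P = 0.1, B = 0, b_increment = 0.12,
                                convention = "standard",
                                placement = c("contiguous", "random"),
                                target_accuracy = NULL,
                                fixed_split = FALSE, reinit_network = TRUE,
                                val_fraction = 0.1,
                                lr = 1e-3, batch_size = 256,
                                snapshot_dir = NULL, seed = NULL,
                                verbose = FALSE) {
  validate_survey_config(config)
  stopifnot(is_count(cycles), cycles >= 1)
  if (!reinit_network) fixed_split <- TRUE
  placement <- match.arg(placement)
  seeds <- config$seeds
  if (!is.null(seed)) {
    seeds <- list(generation = derive_seed(seed, 1),
                  shuffle = derive_seed(seed, 2),
                  split = derive_seed(seed, 3),
                  network = derive_seed(seed, 4))
    config$seeds <- seeds
  }

  db <- generate_primary_database(config)
  db <- balance_classes(db, config$balanced_minority_target)
  targets <- attr(db, "targets")

  subs <- split(db, paste(db$.age_group, db$.outcome))
  subs <- lapply(seq_along(subs), function(k) {
    primary_secondary_shuffle(subs[[k]], seed = derive_seed(seeds$shuffle, -k))
  })
  n_min <- min(vapply(subs, nrow, integer(1)))

  params <- shuffle_params(P = P, B = B, b_increment = b_increment)
  opt <- optimizer_state(P = P, convention = convention)
  spec <- build_loop_network()

  if (!is.null(snapshot_dir) && !dir.exists(snapshot_dir)) {
    dir.create(snapshot_dir, recursive = TRUE)
  }

  records <- vector("list", cycles)
  trace <- vector("list", cycles)
  best_acc <- -Inf
  best_db <- NULL
  best_cycle <- NA_integer_
  n_cycles_run <- 0L
  carried_params <- NULL

  for (cycle in seq_len(cycles)) {
    for (k in seq_along(subs)) {
      subs[[k]] <- shuffle_cycle(subs[[k]], params, placement = placement,
                                 seed = derive_seed(seeds$shuffle, cycle * 64 + k))
    }
    combined <- dplyr::bind_rows(subs)
    attr(combined, "targets") <- targets
    attr(combined, "config_hash") <- attr(db, "config_hash")
    class(combined) <- unique(c("cohort_tbl", class(combined)))

    split_seed <- if (fixed_split) seeds$split else derive_seed(seeds$split, cycle)
    parts <- split_dataset(combined, ratio = 0.8, seed = split_seed,
                           val_fraction = val_fraction)
    fit <- train_network(spec, parts$train, parts$val,
                         epochs = epochs_per_cycle,
                         seed = derive_seed(seeds$network, cycle),
                         lr = lr, batch_size = batch_size,
                         init = if (!reinit_network && cycle > 1) carried_params)
    if (!reinit_network) carried_params <- fit$params
    test_acc <- accuracy(fit, parts$test)
    last <- fit$history[nrow(fit$history), ]

    snapshot_path <- NA_character_
    if (!is.null(snapshot_dir)) {
      snapshot_path <- file.path(snapshot_dir, sprintf("cycle_%03d.csv", cycle))
      export_cohort(combined, snapshot_path)
    }

    n_cycles_run <- cycle
    records[[cycle]] <- tibble::tibble(
      cycle = cycle, P = params$P, B = params$B,
      train_accuracy = last$train_accuracy,
      val_accuracy = if (!is.null(last$val_accuracy)) last$val_accuracy else NA_real_,
      test_accuracy = test_acc,
      snapshot_path = snapshot_path
    )
    if (test_acc > best_acc) {
      best_acc <- test_acc
      best_db <- combined
      best_cycle <- cycle
    }
    if (verbose) {
      message(sprintf("cycle %3d: P = %.3f, B = %.3f, test accuracy = %.4f",
                      cycle, params$P, params$B, test_acc))
    }

    g <- accuracy_gradient(test_acc)
    opt <- update_P(opt, g)
    trace[[cycle]] <- tibble::tibble(
      cycle = cycle, g = g, v = opt$v, s = opt$s,
      delta = attr(opt, "delta"), P_next = opt$omega
    )
    params <- shuffle_params(P = opt$omega, B = params$B,
                             b_increment = params$b_increment)
    params <- advance_B(params, n_min)

    if (!is.null(target_accuracy) && test_acc >= target_accuracy) break
  }

  records <- dplyr::bind_rows(records[seq_len(n_cycles_run)])
  trace <- dplyr::bind_rows(trace[seq_len(n_cycles_run)])
  if (!is.null(snapshot_dir)) {
    jsonlite::stream_out(records, file(file.path(snapshot_dir, "cycles.jsonl")),
                         verbose = FALSE)
  }

  structure(
    list(best_dataset = best_db,
         best_cycle = best_cycle,
         best_test_accuracy = best_acc,
         records = records,
         trace = trace,
         config = config),
    class = "shuffle_loop"
  )
}

#' @export
print.shuffle_loop <- function(x, ...) {
  cat("<shuffle_loop>", nrow(x$records), "cycles over",
      nrow(x$best_dataset), "records\n")
  cat(sprintf("best cycle %d: test accuracy %.4f\n",
              x$best_cycle, x$best_test_accuracy))
  invisible(x)
}
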