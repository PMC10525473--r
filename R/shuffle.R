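# Shuffling operators.  All of them act on one subgroup at a time and are
# exactly marginal-preserving: the total ones-count of every binary column
# and the age multiset are invariant, and the label column is never touched.
# Intervals are 0-based half-open [start, end), matching the window
# arithmetic of the loop controller.

#' Shuffle-window parameters
#'
#' `P` is the window length as a fraction of the subgroup's rows; `B` is
#' the window start as a fraction. The loop starts at `B = 0`, `P = 0.1`,
#' and advances `B` by `b_increment` (default 0.12) each cycle.
#'
#' @param P Window fraction in `(0, 1]`.
#' @param B Window start fraction in `[0, 1)`.
#' @param b_increment Per-cycle additive step for `B`.
#' @return An object of class `shuffle_params`.
#' @export
shuffle_params <- function(P = 0.1, B = 0, b_increment = 0.12) {
  stopifnot(is_scalar_number(P), P > 0, P <= 1,
            is_scalar_number(B), B >= 0, B < 1,
            is_scalar_number(b_increment))
  structure(list(P = P, B = B, b_increment = b_increment),
            class = "shuffle_params")
}

#' @export
print.shuffle_params <- function(x, ...) {
  cat(sprintf("<shuffle_params> P = %.4f, B = %.4f (step %.2f)\n",
              x$P, x$B, x$b_increment))
  invisible(x)
}

#' Fisher-Yates shuffle
#'
#' The classic in-place swap algorithm over R's RNG: uniformly random
#' permutation of the input, preserving the multiset of values.
#'
#' @param x A vector.
#' @param seed Optional integer seed; otherwise the current RNG state is used.
#' @return A permutation of `x`.
#' @export
fisher_yates <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 2) return(x)
  with_seed_(seed, {
    for (i in n:2) {
      j <- sample.int(i, 1L)
      tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
    }
    x
  })
}

#' Deterministic mirror (secondary) shuffle
#'
#' With `sl = floor(length / 2)`, element `i` is swapped with element
#' `sl - i` for `i = 0 .. floor(sl / 2)` (0-based), i.e. the first `sl + 1`
#' elements are reversed. Applied after a Fisher-Yates pass it breaks up
#' the long constant runs a mostly-binary column retains under random
#' permutation. The operator is an involution.
#'
#' @param x A vector of length at least 2.
#' @return The mirrored vector (same multiset of values).
#' @export
secondary_shuffle <- function(x) {
  n <- length(x)
  if (n < 2) stop("secondary_shuffle needs length >= 2", call. = FALSE)
  sl <- n %/% 2
  for (i in 0:(sl %/% 2)) {
    a <- i + 1L; b <- sl - i + 1L
    tmp <- x[a]; x[a] <- x[b]; x[b] <- tmp
  }
  x
}

#' Select the shuffle window for a column of length `n`
#'
#' `start = round(B * n)`, `end = min(start + max(1, round(P * n)), n)`,
#' 0-based half-open; the window is never empty (length floor of one row,
#' start clamped below `n`).
#'
#' @param params A [shuffle_params()].
#' @param n Number of rows.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
select_interval <- function(params, n) {
  stopifnot(is_count(n), n >= 1)
  start <- round(params$B * n)
  start <- min(start, n - 1)
  len <- max(1, round(params$P * n))
  end <- min(start + len, n)
  c(start = as.integer(start), end = as.integer(end))
}

#' Flip the bits of a binary column inside a window
#'
#' `x[i] <- 1 - x[i]` for `i` in `[start, end)` (0-based); entries outside
#' the window are untouched. Applying the flip twice is the identity.
#'
#' @param x A 0/1 vector.
#' @param start,end Window bounds, 0-based half-open.
#' @return The flipped vector.
#' @export
flip_interval <- function(x, start, end) {
  idx <- (start + 1L):end
  w <- x[idx]
  if (!all(w %in% c(0L, 1L))) {
    stop("flip_interval: non-binary value inside the window", call. = FALSE)
  }
  x[idx] <- 1L - w
  x
}

#' Restore a flipped column's total ones-count
#'
#' After [flip_interval()], the window's ones-count changed by
#' `delta = (ones before) - (ones after)`. Compensation converts `delta`
#' entries of the opposite value in the stretch that follows the window,
#' `[end, n)`: by default the first `delta` convertible entries (a
#' contiguous run from the window's endpoint, which is what lets repeated
#' cycles build the long constant runs that make the classes separable);
#' with `placement = "random"` the positions are RNG-chosen instead. If
#' the region cannot absorb the change, the remainder spills into
#' `[0, start)`, and, as a last resort, back into the window itself (a
#' partial un-flip) with a saturation warning. The returned column's total
#' ones-count always equals its pre-flip value.
#'
#' @param x A 0/1 vector whose `[start, end)` window was just flipped.
#' @param start,end Window bounds, 0-based half-open.
#' @param placement `"contiguous"` (default) converts the first
#'   convertible entries after the window; `"random"` picks positions
#'   uniformly at random.
#' @param seed Optional integer seed (only used by `"random"` placement).
#' @return The rebalanced vector, with attribute `saturated = TRUE` when the
#'   window fallback fired.
#' @export
rebalance_column <- function(x, start, end,
                             placement = c("contiguous", "random"),
                             seed = NULL) {
  placement <- match.arg(placement)
  n <- length(x)
  idx <- (start + 1L):end
  ones_after <- sum(x[idx])
  width <- end - start
  delta <- (width - ones_after) - ones_after  # pre-flip minus post-flip ones
  if (delta == 0L) return(x)
  need_val <- if (delta > 0) 0L else 1L      # value to convert away from
  m <- abs(delta)
  regions <- list(
    if (end < n) (end + 1L):n,
    if (start > 0) 1L:start,
    idx                                       # saturation fallback: un-flip
  )
  saturated <- FALSE
  with_seed_(seed, {
    for (r in seq_along(regions)) {
      reg <- regions[[r]]
      if (m == 0L || is.null(reg)) next
      cand <- reg[x[reg] == need_val]
      take <- min(length(cand), m)
      if (take > 0) {
        pick <- if (placement == "contiguous" || length(cand) == 1L) {
          cand[seq_len(take)]
        } else {
          sample(cand, take)
        }
        x[pick] <- 1L - need_val
        m <- m - take
        if (r == 3L) saturated <- TRUE
      }
    }
  })
  if (saturated) {
    warning(warningCondition(
      paste0("rebalance_column: compensation region saturated; ",
             "part of the window flip was reverted to preserve the count"),
      class = "synthcohort_saturation"))
    attr(x, "saturated") <- TRUE
  }
  x
}

#' One main-shuffle pass over a subgroup table
#'
#' Within the window chosen by [select_interval()]: the age column is
#' permuted by [fisher_yates()]; every binary feature column is flipped by
#' [flip_interval()] and then count-compensated by [rebalance_column()],
#' each column independently; the label column is untouched. Every
#' column's total and the age multiset are exactly invariant.
#'
#' @param subgroup A subgroup tibble (the nine cohort columns; provenance
#'   columns are carried through untouched).
#' @param params A [shuffle_params()].
#' @param placement Compensation placement, see [rebalance_column()].
#' @param seed Optional integer seed.
#' @return The shuffled subgroup tibble; columns whose compensation region
#'   saturated (forcing a partial in-window revert) are named in the
#'   `saturated_columns` attribute.
#' @export
shuffle_cycle <- function(subgroup, params,
                          placement = c("contiguous", "random"),
                          seed = NULL) {
  placement <- match.arg(placement)
  assert_cohort(subgroup)
  n <- nrow(subgroup)
  iv <- select_interval(params, n)
  idx <- (iv[["start"]] + 1L):iv[["end"]]
  saturated <- character(0)
  with_seed_(seed, {
    subgroup$age[idx] <- fisher_yates(subgroup$age[idx])
    for (col in binary_feature_columns()) {
      x <- flip_interval(subgroup[[col]], iv[["start"]], iv[["end"]])
      # saturation (a column with no convertible entries outside the window)
      # is tallied on the result rather than escalated per column
      x <- withCallingHandlers(
        rebalance_column(x, iv[["start"]], iv[["end"]], placement = placement),
        synthcohort_saturation = function(w) {
          saturated <<- c(saturated, col)
          invokeRestart("muffleWarning")
        })
      attr(x, "saturated") <- NULL
      subgroup[[col]] <- x
    }
  })
  if (length(saturated) > 0) attr(subgroup, "saturated_columns") <- saturated
  subgroup
}

#' One-time pre-loop randomization of a subgroup table
#'
#' Runs once before the shuffle-train loop: each feature column (age
#' included) is permuted over its full length by [fisher_yates()] and then
#' mirrored by [secondary_shuffle()]. Column totals and multisets are
#' unchanged; only the row-wise pairing of values is randomized.
#'
#' @param subgroup A subgroup tibble.
#' @param seed Optional integer seed.
#' @return The randomized subgroup tibble.
#' @export
primary_secondary_shuffle <- function(subgroup, seed = NULL) {
  assert_cohort(subgroup)
  if (nrow(subgroup) < 2) return(subgroup)
  with_seed_(seed, {
    for (col in feature_columns()) {
      subgroup[[col]] <- secondary_shuffle(fisher_yates(subgroup[[col]]))
    }
  })
  subgroup
}

#' Advance the window start `B` after a cycle
#'
#' `B` grows by the configured increment; wraps by subtracting 1 when it
#' exceeds 1; and resets to 0 when the window it would select (given the
#' current `P`) would overrun the column.
#'
#' @param params A [shuffle_params()].
#' @param n Number of rows the window must fit in.
#' @return A `shuffle_params` with updated `B`.
#' @export
advance_B <- function(params, n) {
  b <- params$B + params$b_increment
  if (b > 1) b <- b - 1
  # overflow test uses the effective window length (floor of one row),
  # matching select_interval, so B = 1 always resets
  if (round(b * n) + max(1, round(params$P * n)) > n) b <- 0
  shuffle_params(P = params$P, B = b, b_increment = params$b_increment)
}
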