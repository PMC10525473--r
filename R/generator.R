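# Primary database generation: summary statistics -> patient-level rows,
# one (age group x outcome) subgroup at a time.  Every stochastic column is
# built by exact-count construction so the generated table reproduces the
# configured marginals to equality, not just in expectation.

#' Sample ages from a bounded age group
#'
#' Draws ages from a normal distribution with the group's mean and SD,
#' truncated to the group's `[lower_bound, upper_bound]` interval, by
#' inverse-CDF sampling. With `sd_age = 0` every draw equals the mean
#' (which must then lie inside the bounds).
#'
#' @param group A one-row data frame or list with `lower_bound`,
#'   `upper_bound`, `mean_age`, `sd_age`.
#' @param n Number of ages to draw.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Numeric vector of `n` ages in years, all inside the bounds.
#' @export
sample_ages <- function(group, n, seed = NULL) {
  stopifnot(is_count(n))
  a <- group$lower_bound; b <- group$upper_bound
  mu <- group$mean_age; sigma <- group$sd_age
  if (sigma < 0) stop("sd_age must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (sigma == 0) {
    if (mu < a || mu > b) {
      stop("degenerate age distribution: sd_age = 0 with mean_age outside [",
           a, ", ", b, "]", call. = FALSE)
    }
    return(rep(mu, n))
  }
  p_lo <- stats::pnorm(a, mu, sigma)
  p_hi <- stats::pnorm(b, mu, sigma)
  if (p_hi - p_lo <= 0) {
    stop("degenerate age distribution: the normal(", mu, ", ", sigma,
         ") places no mass inside [", a, ", ", b, "]", call. = FALSE)
  }
  with_seed_(seed, {
    u <- stats::runif(n, p_lo, p_hi)
    pmin(pmax(stats::qnorm(u, mu, sigma), a), b)
  })
}

# Closed-form mean of normal(mu, sigma) truncated to [a, b]; used by tests
# as the independent oracle for sample_ages.
truncnorm_mean <- function(a, b, mu, sigma) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  mu + sigma * (stats::dnorm(alpha) - stats::dnorm(beta)) / z
}

#' Split an overall exposure prevalence between outcome arms by hazard ratio
#'
#' Treats the published hazard ratio as the risk ratio of developing
#' diabetes for exposed versus unexposed subjects over the study window, and
#' inverts it: with overall exposure prevalence `q`, the prevalence among
#' future diabetics is `hr * q / (1 - q + hr * q)`, and the prevalence among
#' those who stay healthy is whatever conserves the total exposed mass
#' `q * (n_diabetic + n_healthy)` across the two arms. Outputs are clipped
#' to `[0, 1]` with a warning when the requested ratio is unattainable at
#' the given arm sizes.
#'
#' @param hr Hazard ratio (> 0) of the binary exposure.
#' @param overall_prev Overall exposure prevalence `q` in `[0, 1]`.
#' @param n_diabetic,n_healthy Arm sizes (counts, at least one positive).
#' @return Named list with `prev_diabetic` and `prev_healthy`.
#' @export
derive_exposure_split <- function(hr, overall_prev, n_diabetic, n_healthy) {
  if (!is_scalar_number(hr) || hr <= 0) stop("hr must be > 0", call. = FALSE)
  stopifnot(is_scalar_number(overall_prev), overall_prev >= 0, overall_prev <= 1,
            is_count(n_diabetic), is_count(n_healthy), n_diabetic + n_healthy > 0)
  q <- overall_prev
  prev_d <- hr * q / (1 - q + hr * q)
  n_total <- n_diabetic + n_healthy
  prev_h <- if (n_healthy > 0) (q * n_total - prev_d * n_diabetic) / n_healthy
            else q
  clipped <- prev_h < 0 || prev_h > 1 || prev_d < 0 || prev_d > 1
  if (clipped) {
    warning("exposure split clipped to [0, 1]; hr = ", hr, ", q = ", q,
            " is not exactly attainable at these arm sizes", call. = FALSE)
  }
  list(prev_diabetic = min(max(prev_d, 0), 1),
       prev_healthy = min(max(prev_h, 0), 1))
}

# Empirical risk ratio of outcome for exposed vs unexposed, computed from a
# generated age-group pair; the round-trip check for derive_exposure_split.
empirical_hazard_ratio <- function(exposed_diabetic, exposed_healthy,
                                   n_diabetic, n_healthy) {
  exp_tot <- exposed_diabetic + exposed_healthy
  unexp_tot <- (n_diabetic - exposed_diabetic) + (n_healthy - exposed_healthy)
  (exposed_diabetic / exp_tot) /
    ((n_diabetic - exposed_diabetic) / unexp_tot)
}

#' Generate a binary column with an exact count of ones
#'
#' Places exactly `round(n * prevalence)` ones at uniformly random
#' positions. This exact-count construction (rather than independent coin
#' flips) is what makes the generated table's marginal counts reproducible
#' and auditable to equality.
#'
#' @param n Column length.
#' @param prevalence Fraction of ones in `[0, 1]`.
#' @param seed Optional integer seed (otherwise the current RNG state is used).
#' @return Integer vector of `n` zeros and ones.
#' @export
generate_binary_column <- function(n, prevalence, seed = NULL) {
  stopifnot(is_count(n), is_scalar_number(prevalence),
            prevalence >= 0, prevalence <= 1)
  binary_column_exact(n, as.integer(round(n * prevalence)), seed = seed)
}

binary_column_exact <- function(n, ones, seed = NULL) {
  stopifnot(ones >= 0, ones <= n)
  x <- integer(n)
  if (ones > 0 && n > 0) {
    with_seed_(seed, {
      x[sample.int(n, ones)] <- 1L
    })
  }
  x
}

#' Allocate sex counts to the outcome subgroups of an age group
#'
#' The survey publishes male/female counts per age group but not per
#' outcome subgroup; the group's male fraction is carried into both
#' subgroups. The diabetic arm is rounded first and the healthy arm takes
#' the remainder, so the age group's sex totals are conserved exactly.
#'
#' @param group A one-row data frame or list with `n_male`, `n_female`,
#'   `n_healthy`, `n_diabetic`.
#' @return A tibble with columns `outcome` (`"healthy"`, `"diabetic"`),
#'   `n_male`, `n_female`.
#' @export
allocate_gender <- function(group) {
  total <- group$n_healthy + group$n_diabetic
  f <- group$n_male / total
  male_d <- as.integer(round(f * group$n_diabetic))
  male_h <- as.integer(group$n_male - male_d)
  tibble::tibble(
    outcome = c("healthy", "diabetic"),
    n_male = c(male_h, male_d),
    n_female = c(group$n_healthy - male_h, group$n_diabetic - male_d)
  )
}

#' Build the patient-level table for one (age group, outcome) subgroup
#'
#' Ages are drawn from the group's truncated normal and divided by the
#' configured divisor; the sex column (male = 1) carries the exact count
#' from [allocate_gender()]; each binary risk-factor column carries the
#' exact ones-count implied by [derive_exposure_split()] for this outcome
#' arm; the label column is constant (healthy = 0, diabetic = 1).
#'
#' @param group One row of the configuration's `age_groups`.
#' @param outcome `"healthy"` or `"diabetic"`.
#' @param risk_factors The configuration's long `risk_factors` table.
#' @param age_divisor Age normalization divisor.
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows and columns `age`, `gender`, `diet`,
#'   `inactivity`, `alcohol`, `sleep`, `obesity`, `hypertension`, `label`.
#' @export
build_subgroup <- function(group, outcome, risk_factors, age_divisor = 100,
                           seed = NULL) {
  outcome <- match.arg(outcome, c("healthy", "diabetic"))
  n <- if (outcome == "diabetic") group$n_diabetic else group$n_healthy
  n <- as.integer(n)
  gender_alloc <- allocate_gender(group)
  n_male <- gender_alloc$n_male[gender_alloc$outcome == outcome]

  with_seed_(seed, {
    age <- sample_ages(group, n) / age_divisor
    gender <- binary_column_exact(n, n_male)
    cols <- list(age = age, gender = gender)
    for (f in canonical_factors()) {
      row <- risk_factors[risk_factors$factor == f &
                          risk_factors$age_group == group$label, ]
      if (nrow(row) != 1) {
        stop("no hazard ratio/prevalence for factor '", f,
             "' in age group '", group$label, "'", call. = FALSE)
      }
      split <- derive_exposure_split(row$hazard_ratio, row$prevalence,
                                     group$n_diabetic, group$n_healthy)
      prev <- if (outcome == "diabetic") split$prev_diabetic else split$prev_healthy
      cols[[f]] <- generate_binary_column(n, prev)
    }
    cols$label <- rep(if (outcome == "diabetic") 1L else 0L, n)
    tibble::as_tibble(cols)
  })
}

#' Generate the primary database from a survey configuration
#'
#' Builds every (age group, outcome) subgroup with [build_subgroup()] and
#' stacks them into one tibble with provenance columns `.age_group` and
#' `.outcome`. The per-subgroup ones-count of every binary column is
#' recorded in the `targets` attribute, which the conservation audit
#' ([audit_statistics()]) and the shuffle loop check against.
#'
#' @param config A [survey_config()].
#' @return A tibble of class `cohort_tbl`: provenance columns, the eight
#'   feature columns and `label`; attribute `targets` holds the recorded
#'   marginal counts.
#' @export
generate_primary_database <- function(config) {
  validate_survey_config(config)
  seed <- config$seeds$generation
  pieces <- list()
  k <- 0L
  for (i in seq_len(nrow(config$age_groups))) {
    group <- config$age_groups[i, ]
    for (outcome in c("healthy", "diabetic")) {
      k <- k + 1L
      sub <- build_subgroup(group, outcome, config$risk_factors,
                            age_divisor = config$age_divisor,
                            seed = derive_seed(seed, k))
      sub <- tibble::add_column(sub,
                                .age_group = group$label,
                                .outcome = outcome,
                                .before = 1)
      pieces[[k]] <- sub
    }
  }
  db <- dplyr::bind_rows(pieces)
  as_cohort(db, config = config)
}

# Tag a stacked subgroup table as a cohort and (re)record its marginal
# targets: per-subgroup ones-counts of the binary columns and row counts.
as_cohort <- function(data, config = NULL) {
  assert_cohort(data, need_provenance = TRUE)
  attr(data, "targets") <- cohort_marginals(data)
  attr(data, "config_hash") <- if (!is.null(config)) {
    rlang::hash(config_to_list(config))
  } else attr(data, "config_hash")
  class(data) <- unique(c("cohort_tbl", class(data)))
  data
}

#' Per-subgroup marginal counts of a cohort table
#'
#' @param data A cohort tibble with provenance columns.
#' @return A tibble with one row per (age group, outcome, binary column)
#'   giving the ones-count, plus the subgroup row count.
#' @export
cohort_marginals <- function(data) {
  assert_cohort(data, need_provenance = TRUE)
  data |>
    dplyr::group_by(.data$.age_group, .data$.outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(binary_feature_columns()), sum),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(binary_feature_columns()),
                        names_to = "column", values_to = "ones")
}

#' Balance classes by duplicating the minority subgroups
#'
#' Each minority (diabetic) subgroup is replicated whole `floor(k)` times,
#' `k = target / current minority total`; the remaining rows are then
#' apportioned across subgroups by largest remainder, taking the first
#' rows of each subgroup, so the minority total equals `target` exactly.
#' Duplication is deterministic (no RNG). Majority rows are untouched and
#' marginal prevalences are preserved up to the rounding of the remainder
#' rows.
#'
#' @param db A cohort tibble from [generate_primary_database()].
#' @param target Desired minority total (count), or `"match_majority"`.
#' @return The balanced cohort tibble with refreshed `targets`.
#' @export
balance_classes <- function(db, target = "match_majority") {
  assert_cohort(db, need_provenance = TRUE)
  minority <- db[db$.outcome == "diabetic", ]
  majority <- db[db$.outcome == "healthy", ]
  current <- nrow(minority)
  if (identical(target, "match_majority")) target <- nrow(majority)
  stopifnot(is_count(target))
  if (target < current) {
    stop("balancing target (", target, ") is below the current minority size (",
         current, ")", call. = FALSE)
  }
  if (current == 0) stop("no minority rows to balance", call. = FALSE)

  whole <- floor(target / current)
  remainder <- target - whole * current

  subs <- split(minority, minority$.age_group)
  # keep the configured group order
  subs <- subs[unique(minority$.age_group)]
  sizes <- vapply(subs, nrow, integer(1))
  quota <- remainder * sizes / current
  extra <- floor(quota)
  short <- remainder - sum(extra)
  if (short > 0) {
    frac_order <- order(quota - extra, decreasing = TRUE)
    extra[frac_order[seq_len(short)]] <- extra[frac_order[seq_len(short)]] + 1
  }
  balanced_min <- purrr::map2(subs, extra, function(s, e) {
    reps <- s[rep(seq_len(nrow(s)), whole), ]
    if (e > 0) reps <- dplyr::bind_rows(reps, s[seq_len(e), ])
    reps
  })
  out <- dplyr::bind_rows(majority, dplyr::bind_rows(balanced_min))
  out <- as_cohort(out)
  attr(out, "config_hash") <- attr(db, "config_hash")
  out
}

#' Write a cohort table to CSV with a provenance sidecar
#'
#' The CSV carries the canonical header
#' `age,gender,diet,inactivity,alcohol,sleep,obesity,hypertension,label`;
#' subgroup provenance and the recorded marginal targets go to
#' `<path>.provenance.json` so the table can be re-read and audited.
#'
#' @param data A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_cohort <- function(data, path) {
  assert_cohort(data)
  utils::write.csv(data[, c(feature_columns(), "label")], path,
                   row.names = FALSE, quote = FALSE)
  has_prov <- all(provenance_columns() %in% names(data))
  sidecar <- list(
    columns = c(feature_columns(), "label"),
    subgroups = if (has_prov) {
      list(age_group = data$.age_group, outcome = data$.outcome)
    },
    targets = if (has_prov) cohort_marginals(data),
    config_hash = attr(data, "config_hash")
  )
  jsonlite::write_json(sidecar, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort table written by [export_cohort()]
#'
#' @param path CSV path; the `.provenance.json` sidecar is read when present.
#' @return A cohort tibble (with provenance columns when the sidecar exists).
#' @export
read_cohort <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(prov$subgroups)) {
      tab <- tibble::add_column(tab,
                                .age_group = prov$subgroups$age_group,
                                .outcome = prov$subgroups$outcome,
                                .before = 1)
      tab <- as_cohort(tab)
      attr(tab, "config_hash") <- prov$config_hash
    }
  }
  tab
}
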