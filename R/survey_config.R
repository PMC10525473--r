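# Survey configuration: the declarative summary statistics that fully
# parameterize cohort generation.  The whole input surface of the tool is one
# YAML (or JSON) file: age groups with bounds, moments and counts, plus
# per-factor, per-age-group hazard ratios and exposure prevalences.

#' Construct a survey configuration
#'
#' A `survey_config` bundles every summary statistic needed to generate a
#' fully synthetic cohort: an ordered table of age groups (bounds, mean/SD
#' age, outcome subgroup sizes, sex counts) and a long table of binary risk
#' factors (per-age-group hazard ratio and overall exposure prevalence),
#' together with the age normalization divisor, the class-balancing target
#' and named RNG seeds.
#'
#' @param age_groups A data frame with one row per age group and columns
#'   `label`, `lower_bound`, `upper_bound`, `mean_age`, `sd_age`,
#'   `n_healthy`, `n_diabetic`, `n_male`, `n_female`. Bounds are in years;
#'   groups must be non-overlapping, sorted, and lie within 40-100 years.
#' @param risk_factors A data frame in long form with columns `factor`,
#'   `age_group`, `hazard_ratio`, `prevalence`: one row per (factor, age
#'   group). Exactly six factors are required (`diet`, `inactivity`,
#'   `alcohol`, `sleep`, `obesity`, `hypertension`), each with a value for
#'   every configured age group.
#' @param age_divisor Positive scalar the age column is divided by so that
#'   normalized ages lie in (0, 1]; must be at least the largest upper bound.
#'   Default 100.
#' @param balanced_minority_target Total row count the minority (diabetic)
#'   class is duplicated up to, or the string `"match_majority"`.
#' @param seeds Named list of integer seeds: `generation`, `shuffle`,
#'   `split`, `network`.
#' @param metadata Optional list of free-form provenance (e.g. which fields
#'   are placeholders rather than published values).
#'
#' @return A validated object of class `survey_config`.
#' @seealso [load_config()], [save_config()], [diabetes_survey_config()]
#' @export
survey_config <- function(age_groups, risk_factors,
                          age_divisor = 100,
                          balanced_minority_target = "match_majority",
                          seeds = list(generation = 1L, shuffle = 2L,
                                       split = 46L, network = 3L),
                          metadata = list()) {
  cfg <- structure(
    list(
      schema_version = 1L,
      age_groups = tibble::as_tibble(age_groups),
      risk_factors = tibble::as_tibble(risk_factors),
      age_divisor = as.numeric(age_divisor),
      balanced_minority_target = balanced_minority_target,
      seeds = lapply(seeds, as.integer),
      metadata = metadata
    ),
    class = "survey_config"
  )
  validate_survey_config(cfg)
}

canonical_factors <- function() {
  c("diet", "inactivity", "alcohol", "sleep", "obesity", "hypertension")
}

#' Validate a survey configuration
#'
#' Checks every structural invariant of a [survey_config()] and fails with a
#' message listing each violated rule; returns the object invisibly changed
#' (tibbles coerced) when everything holds.
#'
#' @param cfg A `survey_config` (or a plain list with the same fields).
#' @return The validated `survey_config`.
#' @export
validate_survey_config <- function(cfg) {
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  ag <- cfg$age_groups
  required <- c("label", "lower_bound", "upper_bound", "mean_age", "sd_age",
                "n_healthy", "n_diabetic", "n_male", "n_female")
  missing_cols <- setdiff(required, names(ag))
  if (length(missing_cols) > 0) {
    note("age_groups missing columns: ", paste(missing_cols, collapse = ", "))
  } else if (nrow(ag) == 0) {
    note("age_groups must be non-empty")
  } else {
    for (i in seq_len(nrow(ag))) {
      g <- ag[i, ]
      if (!(g$lower_bound < g$upper_bound)) {
        note("group '", g$label, "': lower_bound must be < upper_bound")
      }
      if (g$lower_bound < 40) {
        note("group '", g$label, "': lower_bound must be >= 40")
      }
      if (g$upper_bound > 100) {
        note("group '", g$label, "': upper_bound must be <= 100")
      }
      counts <- c(g$n_healthy, g$n_diabetic, g$n_male, g$n_female)
      if (any(!vapply(counts, is_count, logical(1)))) {
        note("group '", g$label, "': counts must be non-negative integers")
      }
      if (g$n_male + g$n_female != g$n_healthy + g$n_diabetic) {
        note("group '", g$label, "': n_male + n_female (", g$n_male + g$n_female,
             ") must equal n_healthy + n_diabetic (", g$n_healthy + g$n_diabetic, ")")
      }
      if (g$sd_age < 0) note("group '", g$label, "': sd_age must be >= 0")
    }
    if (is.unsorted(ag$lower_bound, strictly = TRUE)) {
      note("age_groups must be sorted by lower_bound")
    }
    if (nrow(ag) > 1 && any(ag$upper_bound[-nrow(ag)] > ag$lower_bound[-1])) {
      note("age_groups must not overlap")
    }
    if (anyDuplicated(ag$label)) note("age group labels must be unique")
    if (!is_scalar_number(cfg$age_divisor) || cfg$age_divisor <= 0) {
      note("age_divisor must be a positive number")
    } else if (max(ag$upper_bound) > cfg$age_divisor) {
      note("age_divisor must be >= the largest upper_bound so normalized ages are <= 1")
    }
  }

  rf <- cfg$risk_factors
  rf_cols <- c("factor", "age_group", "hazard_ratio", "prevalence")
  if (!all(rf_cols %in% names(rf))) {
    note("risk_factors missing columns: ",
         paste(setdiff(rf_cols, names(rf)), collapse = ", "))
  } else {
    fac <- unique(rf$factor)
    if (!identical(sort(fac), sort(canonical_factors()))) {
      note("risk_factors must contain exactly the six factors: ",
           paste(canonical_factors(), collapse = ", "))
    }
    if (any(rf$hazard_ratio <= 0, na.rm = TRUE) || anyNA(rf$hazard_ratio)) {
      note("every hazard_ratio must be a positive number")
    }
    if (anyNA(rf$prevalence) || any(rf$prevalence < 0 | rf$prevalence > 1)) {
      note("every prevalence must lie in [0, 1]")
    }
    if (length(missing_cols) == 0 && nrow(ag) > 0) {
      for (f in fac) {
        absent <- setdiff(ag$label, rf$age_group[rf$factor == f])
        if (length(absent) > 0) {
          note("factor '", f, "' lacks values for age group(s): ",
               paste(absent, collapse = ", "))
        }
      }
    }
  }

  tgt <- cfg$balanced_minority_target
  if (!(identical(tgt, "match_majority") || is_count(tgt))) {
    note("balanced_minority_target must be a non-negative count or \"match_majority\"")
  }
  needed_seeds <- c("generation", "shuffle", "split", "network")
  if (!all(needed_seeds %in% names(cfg$seeds))) {
    note("seeds must name: ", paste(needed_seeds, collapse = ", "))
  }

  if (length(problems) > 0) {
    stop("invalid survey configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config> schema", x$schema_version, "\n")
  cat(nrow(x$age_groups), "age groups,",
      length(unique(x$risk_factors$factor)), "risk factors\n")
  cat("healthy:", sum(x$age_groups$n_healthy),
      " diabetic:", sum(x$age_groups$n_diabetic),
      " balance target:", format(x$balanced_minority_target), "\n")
  print(x$age_groups, ...)
  invisible(x)
}

config_to_list <- function(cfg) {
  ag <- lapply(seq_len(nrow(cfg$age_groups)), function(i) {
    g <- as.list(cfg$age_groups[i, ])
    g
  })
  rf <- lapply(unique(cfg$risk_factors$factor), function(f) {
    sub <- cfg$risk_factors[cfg$risk_factors$factor == f, ]
    list(
      name = f,
      hazard_ratio_by_group = stats::setNames(as.list(sub$hazard_ratio), sub$age_group),
      prevalence_by_group = stats::setNames(as.list(sub$prevalence), sub$age_group)
    )
  })
  list(
    schema_version = cfg$schema_version,
    age_divisor = cfg$age_divisor,
    balanced_minority_target = cfg$balanced_minority_target,
    seeds = cfg$seeds,
    metadata = cfg$metadata,
    age_groups = ag,
    risk_factors = rf
  )
}

config_from_list <- function(lst, source = "config") {
  if (is.null(lst$schema_version)) {
    stop("config '", source, "': schema_version field is required", call. = FALSE)
  }
  ag <- dplyr::bind_rows(lapply(lst$age_groups, tibble::as_tibble))
  rf <- dplyr::bind_rows(lapply(lst$risk_factors, function(f) {
    groups <- names(f$hazard_ratio_by_group)
    tibble::tibble(
      factor = f$name,
      age_group = groups,
      hazard_ratio = as.numeric(unlist(f$hazard_ratio_by_group[groups])),
      prevalence = as.numeric(unlist(f$prevalence_by_group[groups]))
    )
  }))
  survey_config(
    age_groups = ag,
    risk_factors = rf,
    age_divisor = lst$age_divisor %||% 100,
    balanced_minority_target = lst$balanced_minority_target %||% "match_majority",
    seeds = lst$seeds %||% list(generation = 1L, shuffle = 2L,
                                split = 46L, network = 3L),
    metadata = lst$metadata %||% list()
  )
}

#' Read a survey configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`); the
#' result is validated before it is returned, and a configuration written by
#' [save_config()] loads back field-for-field identical.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated [survey_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- tryCatch(
    if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(e) {
      stop("could not parse '", path, "' as ",
           if (ext == "json") "JSON" else "YAML", ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  config_from_list(lst, source = path)
}

#' Write a survey configuration to YAML or JSON
#'
#' @param cfg A [survey_config()].
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_survey_config(cfg)
  lst <- config_to_list(cfg)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' The packaged diabetes-survey configuration
#'
#' Loads the summary statistics of the 5-year type 2 diabetes incidence
#' survey that ships with the package: four age groups (40 to <55, 55 to
#' <65, 65 to <75, at least 75 years) with their published subgroup and sex
#' counts, and six binary risk factors. The survey publishes the counts
#' directly; the per-factor hazard ratios, exposure prevalences and age
#' moments are documented synthetic placeholders (flagged
#' `user_supplied: false` in the metadata) and should be replaced with the
#' survey's own values for substantive use.
#'
#' @return A validated [survey_config()] with 4 age groups, 87,601 healthy
#'   and 6,163 diabetic records, and a minority balancing target of 84,692.
#' @export
diabetes_survey_config <- function() {
  load_config(system.file("extdata", "diabetes_survey.yaml",
                          package = "synthcohort", mustWork = TRUE))
}

#' Scale a configuration's subgroup counts down proportionally
#'
#' Produces a smaller study with the same structure: every subgroup count,
#' sex count and the minority balancing target are multiplied by the same
#' factor and rounded, preserving within-group proportions (sex totals are
#' re-derived so the count identity still holds). Useful for desk-scale
#' experiments with the full pipeline.
#'
#' @param cfg A [survey_config()].
#' @param total_records Approximate total row count of the final balanced
#'   dataset (majority plus balanced minority) to aim for.
#' @return A validated `survey_config` with scaled counts.
#' @export
scale_config <- function(cfg, total_records) {
  validate_survey_config(cfg)
  tgt <- cfg$balanced_minority_target
  n_major <- sum(cfg$age_groups$n_healthy)
  n_minor <- if (identical(tgt, "match_majority")) n_major else tgt
  s <- total_records / (n_major + n_minor)
  ag <- cfg$age_groups
  ag$n_healthy <- pmax(1L, as.integer(round(ag$n_healthy * s)))
  ag$n_diabetic <- pmax(1L, as.integer(round(ag$n_diabetic * s)))
  # keep the sex split proportional, then force the count identity
  male_frac <- cfg$age_groups$n_male /
    (cfg$age_groups$n_healthy + cfg$age_groups$n_diabetic)
  total <- ag$n_healthy + ag$n_diabetic
  ag$n_male <- as.integer(round(male_frac * total))
  ag$n_female <- as.integer(total - ag$n_male)
  new_target <- if (identical(tgt, "match_majority")) "match_majority"
                else as.integer(round(tgt * s))
  survey_config(
    age_groups = ag,
    risk_factors = cfg$risk_factors,
    age_divisor = cfg$age_divisor,
    balanced_minority_target = new_target,
    seeds = cfg$seeds,
    metadata = c(cfg$metadata, list(scaled_by = s))
  )
}
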