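# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing determinism contracts route through this.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific seed from a base seed and an offset; result stays
# inside the 32-bit signed integer range R's set.seed() accepts.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629L)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Feature columns of a cohort table, in canonical order.
feature_columns <- function() {
  c("age", "gender", "diet", "inactivity", "alcohol", "sleep",
    "obesity", "hypertension")
}

binary_feature_columns <- function() setdiff(feature_columns(), "age")

provenance_columns <- function() c(".age_group", ".outcome")

assert_cohort <- function(data, need_provenance = FALSE) {
  missing_cols <- setdiff(c(feature_columns(), "label"), names(data))
  if (length(missing_cols) > 0) {
    stop("not a cohort table; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (need_provenance && !all(provenance_columns() %in% names(data))) {
    stop("cohort table lacks subgroup provenance columns (.age_group, .outcome)",
         call. = FALSE)
  }
  invisible(data)
}
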