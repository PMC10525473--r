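# Fixtures built in code: a desk-scale copy of the packaged survey, random
# subgroup tables for property sweeps, and a separable two-blob dataset
# that serves as the training oracle.

small_survey <- function(total = 600) {
  scale_config(diabetes_survey_config(), total)
}

# A random subgroup table in cohort layout: uniform ages, binary factor
# columns at random prevalences, constant label.
random_subgroup <- function(n, label = 1L) {
  cols <- list(age = round(stats::runif(n, 0.4, 1), 4))
  for (f in c("gender", "diet", "inactivity", "alcohol", "sleep",
              "obesity", "hypertension")) {
    cols[[f]] <- generate_binary_column(n, stats::runif(1))
  }
  cols$label <- rep(label, n)
  tibble::as_tibble(cols)
}

# Two well-separated Gaussian blobs in the 8 feature columns; linearly
# separable, so any working trainer should exceed 95% accuracy quickly.
make_blobs <- function(n, sep = 3, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  half <- n / 2
  feats <- synthcohort:::feature_columns()
  X <- rbind(
    matrix(stats::rnorm(half * 8, mean = 0), half, 8),
    matrix(stats::rnorm(half * 8, mean = sep), half, 8)
  )
  colnames(X) <- feats
  out <- tibble::as_tibble(X)
  out$label <- rep(c(0L, 1L), each = half)
  out[sample.int(n), ]
}
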