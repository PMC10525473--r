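test_that("sample_ages follows the truncated normal law within its bounds", {
  group <- list(lower_bound = 40, upper_bound = 55, mean_age = 47.2, sd_age = 4.2)

  ages <- sample_ages(group, 10000, seed = 11)
  expect_true(all(ages >= 40 & ages <= 55))
  # closed-form truncated-normal mean as the oracle
  mu_trunc <- synthcohort:::truncnorm_mean(40, 55, 47.2, 4.2)
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - mu_trunc), 3 * se)

  # zero-variance limit and empty draw
  degenerate <- list(lower_bound = 40, upper_bound = 55, mean_age = 50, sd_age = 0)
  expect_equal(sample_ages(degenerate, 5, seed = 1), rep(50, 5))
  expect_equal(sample_ages(group, 0, seed = 1), numeric(0))
  expect_identical(sample_ages(group, 50, seed = 3), sample_ages(group, 50, seed = 3))

  bad <- list(lower_bound = 40, upper_bound = 55, mean_age = 80, sd_age = 0)
  expect_error(sample_ages(bad, 5), "degenerate")
})

test_that("derive_exposure_split inverts the hazard ratio and conserves mass", {
  # null effect: both arms keep the overall prevalence
  for (q in c(0.1, 0.5, 0.9)) {
    s <- derive_exposure_split(1, q, 500, 5000)
    expect_equal(s$prev_diabetic, q)
    expect_equal(s$prev_healthy, q)
  }

  # closed form at hr = 2, q = 0.5
  s <- derive_exposure_split(2, 0.5, 1000, 1000)
  expect_equal(s$prev_diabetic, 2 * 0.5 / (0.5 + 2 * 0.5), tolerance = 1e-12)
  # mass conservation
  expect_equal(0.5 * 2000, s$prev_diabetic * 1000 + s$prev_healthy * 1000)

  expect_error(derive_exposure_split(0, 0.5, 10, 10), "hr")
  expect_warning(derive_exposure_split(10, 0.3, 9000, 1000), "clipped")
})

test_that("generated arms recover the configured hazard ratio", {
  # round-trip: build exact-count arms at the derived prevalences and
  # recompute the empirical risk ratio from the resulting 2x2 counts
  n <- 10000
  for (hr in c(0.5, 2, 4)) {
    # q = 0.5 keeps every ratio attainable at equal arms
    s <- derive_exposure_split(hr, 0.5, n, n)
    ed <- sum(generate_binary_column(n, s$prev_diabetic, seed = 5))
    eh <- sum(generate_binary_column(n, s$prev_healthy, seed = 6))
    hr_hat <- synthcohort:::empirical_hazard_ratio(ed, eh, n, n)
    expect_lt(abs(hr_hat / hr - 1), 0.05)
  }
})

test_that("binary columns carry an exact ones-count", {
  expect_equal(sum(generate_binary_column(10, 0, seed = 1)), 0)
  expect_equal(sum(generate_binary_column(10, 1, seed = 1)), 10)
  expect_equal(sum(generate_binary_column(1000, 0.3, seed = 1)), 300)
  expect_equal(sum(generate_binary_column(1000, 0.2345, seed = 2)), round(234.5))
})

test_that("gender allocation keeps the age-group male fraction in both arms", {
  cfg <- diabetes_survey_config()
  diabetic_males <- vapply(seq_len(4), function(i) {
    a <- allocate_gender(cfg$age_groups[i, ])
    a$n_male[a$outcome == "diabetic"]
  }, integer(1))
  expect_equal(diabetic_males, c(673L, 852L, 484L, 87L))
  # totals conserved exactly
  for (i in seq_len(4)) {
    a <- allocate_gender(cfg$age_groups[i, ])
    expect_equal(sum(a$n_male), cfg$age_groups$n_male[i])
    expect_equal(sum(a$n_female), cfg$age_groups$n_female[i])
  }
  # all-male group
  g <- list(n_healthy = 70L, n_diabetic = 30L, n_male = 100L, n_female = 0L)
  a <- allocate_gender(g)
  expect_equal(a$n_male[a$outcome == "diabetic"], 30L)
})

test_that("build_subgroup produces the configured rows with exact marginals", {
  cfg <- diabetes_survey_config()
  g4 <- cfg$age_groups[4, ]
  sub <- build_subgroup(g4, "diabetic", cfg$risk_factors, seed = 9)
  expect_equal(nrow(sub), 203)
  expect_true(all(sub$age >= 0.75 & sub$age <= 1.00))
  expect_true(all(sub$label == 1L))
  # column sums match the exact-count targets
  a <- allocate_gender(g4)
  expect_equal(sum(sub$gender), a$n_male[a$outcome == "diabetic"])
  for (f in c("diet", "obesity")) {
    row <- cfg$risk_factors[cfg$risk_factors$factor == f &
                            cfg$risk_factors$age_group == g4$label, ]
    s <- derive_exposure_split(row$hazard_ratio, row$prevalence,
                               g4$n_diabetic, g4$n_healthy)
    expect_equal(sum(sub[[f]]), round(203 * s$prev_diabetic))
  }
})

test_that("the primary database is auditable by construction", {
  cfg <- small_survey(800)
  db <- generate_primary_database(cfg)
  expect_equal(nrow(db), sum(cfg$age_groups$n_healthy) +
                 sum(cfg$age_groups$n_diabetic))
  expect_true(audit_passed(audit_statistics(db)))
  # deterministic given the configured seeds
  db2 <- generate_primary_database(cfg)
  expect_equal(as.data.frame(db), as.data.frame(db2))
})

test_that("class balancing reaches the target exactly and keeps prevalences", {
  cfg <- small_survey(800)
  db <- generate_primary_database(cfg)
  n_min <- sum(db$.outcome == "diabetic")

  # identity at target = current
  same <- balance_classes(db, n_min)
  expect_equal(nrow(same), nrow(db))

  target <- cfg$balanced_minority_target
  bal <- balance_classes(db, target)
  expect_equal(sum(bal$.outcome == "diabetic"), target)
  expect_equal(sum(bal$.outcome == "healthy"), sum(db$.outcome == "healthy"))

  # replication changes per-column prevalence only within remainder rounding
  for (col in c("diet", "hypertension")) {
    before <- mean(db[[col]][db$.outcome == "diabetic"])
    after <- mean(bal[[col]][bal$.outcome == "diabetic"])
    expect_lt(abs(before - after), n_min / target)
  }
  expect_error(balance_classes(db, n_min - 1), "below")
})

test_that("full-scale balancing reproduces the published minority total", {
  cfg <- diabetes_survey_config()
  # counts only, no patient rows: apportion exactly as balance_classes does
  sizes <- cfg$age_groups$n_diabetic
  current <- sum(sizes)
  target <- cfg$balanced_minority_target
  whole <- floor(target / current)
  remainder <- target - whole * current
  quota <- remainder * sizes / current
  extra <- floor(quota)
  short <- remainder - sum(extra)
  ord <- order(quota - extra, decreasing = TRUE)
  extra[ord[seq_len(short)]] <- extra[ord[seq_len(short)]] + 1
  expect_equal(sum(sizes * whole + extra), 84692)
})

test_that("cohort CSV export round-trips with provenance", {
  cfg <- small_survey(400)
  db <- generate_primary_database(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  export_cohort(db, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
               "age,gender,diet,inactivity,alcohol,sleep,obesity,hypertension,label")
  back <- read_cohort(path)
  expect_equal(back$.age_group, db$.age_group)
  expect_equal(back$diet, db$diet)
  expect_true(audit_passed(audit_statistics(back)))
})
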