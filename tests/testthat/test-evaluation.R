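test_that("identical class distributions give overlap 1, disjoint give 0", {
  base <- make_blobs(400, sep = 0)        # same distribution in both classes
  base[synthcohort:::feature_columns()] <-
    round(base[synthcohort:::feature_columns()])
  h1 <- class_score_histograms(dplyr::bind_rows(
    dplyr::mutate(base, label = 0L), dplyr::mutate(base, label = 1L)))
  expect_equal(h1$overlap_coefficient, 1)

  far <- make_blobs(400, sep = 50)        # scores cannot overlap
  h0 <- class_score_histograms(far)
  expect_equal(h0$overlap_coefficient, 0)

  # counts partition the rows
  expect_equal(h0$n_class0 + h0$n_class1, 400)
  expect_equal(sum(h0$class0_counts), sum(far$label == 0))
})

test_that("overlap matches the closed-form Gaussian value", {
  # class scores ~ N(0,1) vs N(4,1): overlap = 2 * pnorm(-2)
  set.seed(77)
  n <- 100000
  feats <- synthcohort:::feature_columns()
  d <- tibble::as_tibble(matrix(0, 2 * n, 8, dimnames = list(NULL, feats)))
  d$age <- c(stats::rnorm(n, 0), stats::rnorm(n, 4))
  d$label <- rep(c(0L, 1L), each = n)
  h <- class_score_histograms(d)
  expect_equal(h$overlap_coefficient, 2 * stats::pnorm(-2), tolerance = 0.01)
})

test_that("overlap shrinks as class score distributions move apart", {
  set.seed(3)
  overlaps <- vapply(c(0, 1, 2, 4), function(sep) {
    class_score_histograms(make_blobs(2000, sep = sep))$overlap_coefficient
  }, numeric(1))
  expect_true(all(diff(overlaps) <= 0))
})

test_that("binning is invariant to row order and single classes are flagged", {
  d <- make_blobs(300, sep = 2)
  h <- class_score_histograms(d)
  h_perm <- class_score_histograms(d[sample.int(300), ])
  expect_equal(h$class0_counts, h_perm$class0_counts)
  expect_equal(h$class1_counts, h_perm$class1_counts)

  solo <- d[d$label == 1, ]
  h_solo <- class_score_histograms(solo)
  expect_true(is.na(h_solo$overlap_coefficient))
})

test_that("the conservation audit is exact and sensitive to single bits", {
  cfg <- small_survey(600)
  db <- generate_primary_database(cfg)
  expect_true(audit_passed(audit_statistics(db)))

  corrupted <- db
  i <- which(corrupted$diet == 0)[1]
  corrupted$diet[i] <- 1L
  audit <- audit_statistics(corrupted, targets = attr(db, "targets"))
  expect_false(audit_passed(audit))
  expect_equal(sum(audit$difference != 0), 1)
  expect_equal(audit$column[audit$difference != 0], "diet")

  no_prov <- db[, setdiff(names(db), ".age_group")]
  expect_error(audit_statistics(no_prov), "provenance")
})

test_that("audit still passes after many shuffle cycles", {
  cfg <- small_survey(500)
  db <- balance_classes(generate_primary_database(cfg),
                        cfg$balanced_minority_target)
  targets <- attr(db, "targets")
  subs <- split(db, paste(db$.age_group, db$.outcome))
  params <- shuffle_params(P = 0.3, B = 0)
  for (cycle in 1:20) {
    subs <- lapply(subs, shuffle_cycle, params = params)
    params <- advance_B(params, min(vapply(subs, nrow, integer(1))))
  }
  after <- dplyr::bind_rows(subs)
  expect_true(audit_passed(audit_statistics(after, targets = targets)))
})

test_that("evaluate_best trains the deeper network and reports per epoch", {
  blobs <- make_blobs(1000, sep = 3)
  ev <- evaluate_best(blobs, epochs = 5, seed = 46, lr = 0.01, batch_size = 64)
  expect_equal(nrow(ev$history), 5)
  expect_gt(ev$test_accuracy, 0.95)           # separable oracle problem
  expect_equal(ev$spec$layer_sizes, c(8L, 16L, 64L, 32L, 16L, 1L))

  ev0 <- evaluate_best(blobs, epochs = 0, seed = 46)
  expect_equal(nrow(ev0$history), 0)
  expect_lt(abs(ev0$test_accuracy - 0.5), 0.35)  # untrained: near chance
})
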