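test_that("fisher_yates permutes without changing the multiset", {
  expect_equal(fisher_yates(c(7)), c(7))
  x <- stats::rnorm(200)
  y <- fisher_yates(x, seed = 4)
  expect_equal(sort(y), sort(x))
  expect_false(identical(y, x))
  expect_identical(fisher_yates(x, seed = 4), y)
})

test_that("fisher_yates agrees with sample() on permutation statistics", {
  # cross-check against R's own uniform permutation: mean displacement of
  # each element over many shuffles matches
  set.seed(99)
  n <- 6
  pos_fy <- matrix(0, n, n)
  pos_sp <- matrix(0, n, n)
  for (r in 1:3000) {
    i_fy <- cbind(fisher_yates(1:n), 1:n)
    i_sp <- cbind(sample(1:n), 1:n)
    pos_fy[i_fy] <- pos_fy[i_fy] + 1
    pos_sp[i_sp] <- pos_sp[i_sp] + 1
  }
  # every (value, position) cell should be ~ uniform 1/n for both
  expect_lt(max(abs(pos_fy / 3000 - 1 / n)), 0.05)
  expect_lt(max(abs(pos_fy - pos_sp) / 3000), 0.07)
})

test_that("secondary shuffle is the documented mirror and an involution", {
  expect_equal(secondary_shuffle(c(0, 1, 2, 3, 4, 5)), c(3, 2, 1, 0, 4, 5))
  for (n in c(2, 3, 5, 8, 13)) {
    x <- seq_len(n)
    y <- secondary_shuffle(x)
    expect_equal(sort(y), sort(x))
    expect_equal(secondary_shuffle(y), x)
  }
  expect_error(secondary_shuffle(1), "length")
})

test_that("select_interval implements the stated window rule", {
  expect_equal(unname(select_interval(shuffle_params(P = 0.1, B = 0.5), 1000)),
               c(500L, 600L))
  expect_equal(unname(select_interval(shuffle_params(P = 0.1, B = 0.99), 1000)),
               c(990L, 1000L))
  expect_equal(unname(select_interval(shuffle_params(P = 0.01, B = 0), 10)),
               c(0L, 1L))
  # never empty, always inside [0, n]
  set.seed(21)
  for (r in 1:200) {
    n <- sample(1:500, 1)
    iv <- select_interval(shuffle_params(P = stats::runif(1, 0.01, 1),
                                         B = stats::runif(1, 0, 0.999)), n)
    expect_true(iv[["start"]] >= 0 && iv[["start"]] < iv[["end"]] &&
                  iv[["end"]] <= n)
  }
})

test_that("flip_interval complements the window and nothing else", {
  x <- c(1L, 1L, 0L, 0L, 1L, 0L)
  y <- flip_interval(x, 1, 4)
  expect_equal(y, c(1L, 0L, 1L, 1L, 1L, 0L))
  expect_equal(flip_interval(y, 1, 4), x)           # involution
  w <- rep(1L, 5)
  expect_equal(sum(flip_interval(w, 0, 5)), 0)
  expect_error(flip_interval(c(0, 2, 1), 0, 3), "non-binary")
})

test_that("rebalance_column restores the exact ones-count", {
  # hand-traced case: 10 ones then 10 zeros, flip [0, 10)
  x <- c(rep(1L, 10), rep(0L, 10))
  flipped <- flip_interval(x, 0, 10)
  expect_equal(sum(flipped), 0)
  out <- rebalance_column(flipped, 0, 10)
  expect_equal(sum(out), 10)
  # contiguous placement converts the run right after the window
  expect_equal(out, c(rep(0L, 10), rep(1L, 10)))

  # balanced window needs no compensation
  x2 <- c(0L, 1L, 0L, 1L, 0L, 0L)
  f2 <- flip_interval(x2, 0, 4)
  expect_equal(rebalance_column(f2, 0, 4), f2)

  # property sweep over random columns, windows and both placements
  set.seed(31)
  for (r in 1:1000) {
    n <- sample(10:100, 1)
    x <- generate_binary_column(n, stats::runif(1, 0.05, 0.95))
    iv <- select_interval(shuffle_params(P = stats::runif(1, 0.01, 0.8),
                                         B = stats::runif(1, 0, 0.99)), n)
    f <- flip_interval(x, iv[["start"]], iv[["end"]])
    pl <- if (r %% 2 == 0) "contiguous" else "random"
    out <- suppressWarnings(rebalance_column(f, iv[["start"]], iv[["end"]],
                                             placement = pl))
    expect_equal(sum(out), sum(x))
  }
})

test_that("shuffle_cycle conserves every marginal and the label column", {
  set.seed(41)
  for (r in 1:50) {
    sub <- random_subgroup(sample(20:200, 1))
    params <- shuffle_params(P = stats::runif(1, 0.01, 1),
                             B = stats::runif(1, 0, 0.99))
    out <- shuffle_cycle(sub, params, seed = r)
    for (col in c("gender", "diet", "inactivity", "alcohol", "sleep",
                  "obesity", "hypertension")) {
      expect_identical(sum(out[[col]]), sum(sub[[col]]))
    }
    expect_identical(sort(out$age), sort(sub$age))
    expect_identical(out$label, sub$label)
  }
})

test_that("one-row windows leave age alone but keep counts", {
  sub <- random_subgroup(50)
  out <- shuffle_cycle(sub, shuffle_params(P = 0.01, B = 0.5), seed = 1)
  iv <- select_interval(shuffle_params(P = 0.01, B = 0.5), 50)
  expect_equal(iv[["end"]] - iv[["start"]], 1L)
  expect_equal(sort(out$age), sort(sub$age))
  expect_equal(sum(out$diet), sum(sub$diet))
})

test_that("primary_secondary_shuffle randomizes pairing, not marginals", {
  sub <- random_subgroup(100)
  out <- primary_secondary_shuffle(sub, seed = 8)
  for (col in c("age", "gender", "diet", "obesity")) {
    expect_equal(sort(out[[col]]), sort(sub[[col]]))
  }
  expect_identical(out$label, sub$label)
  expect_false(identical(out$age, sub$age))
})

test_that("advance_B follows the increment, wrap and reset rules", {
  n <- 1000
  p <- shuffle_params(P = 0.1, B = 0)
  expect_equal(advance_B(p, n)$B, 0.12)
  # wrap past 1
  p95 <- shuffle_params(P = 0.1, B = 0.95)
  expect_equal(advance_B(p95, n)$B, 0.07, tolerance = 1e-12)
  # window would overrun: reset to zero
  pbig <- shuffle_params(P = 0.6, B = 0.5)
  expect_equal(advance_B(pbig, n)$B, 0)
  # B = 1.00 exactly (0.88 + 0.12) also resets
  p88 <- shuffle_params(P = 0.1, B = 0.88)
  expect_equal(advance_B(p88, n)$B, 0)
})
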