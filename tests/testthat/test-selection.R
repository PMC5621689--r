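test_that("a planted mean-shift feature outranks pure noise almost surely", {
  wins <- 0
  for (s in 1:100) {
    set.seed(500 + s)
    y <- rep(c(1, -1), each = 100)
    x <- cbind(c(rnorm(100, 3), rnorm(100)), rnorm(200))
    rk <- rank_features(x, y)
    wins <- wins + (rk$order[1] == 1)
  }
  expect_gte(wins, 95)
})

test_that("CBR keeps a duplicated informative pair through round one", {
  set.seed(42)
  sig <- c(rnorm(100, 3), rnorm(100))
  x <- cbind(sig, sig, rnorm(200), rnorm(200))
  y <- rep(c(1, -1), each = 100)
  rk <- rank_features(x, y, control = rfe_control(step_fraction = 0.3))
  # round 1 must eliminate a noise feature, never a duplicate
  expect_false(any(rk$round[1:2] == 1))
  expect_setequal(rk$order[1:2], 1:2)
  # without CBR the diluted duplicates are not shielded as a group
  rk2 <- rank_features(x, y, control = rfe_control(step_fraction = 0.3,
                                                   cbr = FALSE))
  expect_true(is.integer(rk2$order))
})

test_that("single-feature input yields the trivial ranking", {
  set.seed(71)
  x <- matrix(rnorm(20), ncol = 1)
  rk <- rank_features(x, rep(c(1, -1), 10))
  expect_equal(rk$order, 1L)
})

test_that("ranking is a permutation; CBR off equals CBR on without correlation", {
  set.seed(72)
  x <- matrix(rnorm(100 * 15), 100)
  y <- rep(c(1, -1), 50)
  x[y == 1, 1:3] <- x[y == 1, 1:3] + 2
  r1 <- rank_features(x, y)
  expect_equal(sort(r1$order), 1:15)
  r2 <- rank_features(x, y, control = rfe_control(cbr = FALSE))
  expect_identical(r1$order, r2$order)
  expect_identical(rank_features(x, y)$order, r1$order)  # deterministic
})

test_that("constant columns are warned about and ranked last", {
  set.seed(73)
  x <- cbind(matrix(rnorm(40 * 3), 40), 7)
  y <- rep(c(1, -1), 20)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  expect_warning(rk <- rank_features(x, y), "constant")
  expect_equal(rk$order[4], 4L)
  expect_equal(rk$order[1], 1L)
})

test_that("top-k selection is prefix-consistent with block bookkeeping", {
  set.seed(74)
  x <- matrix(rnorm(60 * 12), 60)
  attr(x, "block_map") <- data.frame(block = c("nmbac", "dct"),
                                     start = c(1L, 9L), end = c(8L, 12L))
  y <- rep(c(1, -1), 30)
  x[y == 1, c(2, 10)] <- x[y == 1, c(2, 10)] + 2
  rk <- rank_features(x, y)
  expect_equal(unname(as.vector(block_counts(rk))), c(8, 4))
  s5 <- select_top_k(rk, 5, x)
  s3 <- select_top_k(rk, 3, x)
  expect_equal(s5$map$index[1:3], s3$map$index)
  expect_equal(s3$matrix, s5$matrix[, 1:3])
  sp <- select_top_k(rk, 12, x)
  expect_setequal(sp$map$index, 1:12)         # full selection permutes
  expect_true(all(s3$map$block %in% c("nmbac", "dct")))
  expect_error(select_top_k(rk, 13, x), "out of range")
  expect_error(select_top_k(rk, 0, x), "out of range")
})

test_that("accuracy over k plateaus once the informative support is covered", {
  set.seed(75)
  n <- 120; p <- 40
  x <- matrix(rnorm(n * p), n)
  y <- rep(c(1, -1), n / 2)
  x[y == 1, 1:5] <- x[y == 1, 1:5] + 2
  rk <- rank_features(x, y, stop_at = 2)
  tab <- sweep_k(x, y, rk, k_grid = c(2, 5, 10, 20, 40), seed = 4)
  expect_equal(tab$k, c(2, 5, 10, 20, 40))
  expect_lte(attr(tab, "best_k"), 20)
  expect_gte(max(tab$ACC[tab$k >= 5]), 0.9)
  expect_error(sweep_k(x, y, rk, k_grid = integer(0)), "empty")
})

test_that("sweeping k = p reproduces the no-selection evaluation", {
  set.seed(76)
  x <- matrix(rnorm(60 * 6), 60)
  y <- rep(c(1, -1), 30)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  rk <- rank_features(x, y)
  tab <- sweep_k(x, y, rk, k_grid = 6, seed = 5)
  direct <- cv_eval(select_top_k(rk, 6, x)$matrix, y, seed = 5)
  expect_equal(tab$ACC, direct$metrics$ACC)
  expect_equal(tab$MCC, direct$metrics$MCC)
})

test_that("single-class labels are rejected", {
  x <- matrix(rnorm(40), 10)
  expect_error(rank_features(x, rep(1, 10)), "both classes")
})
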