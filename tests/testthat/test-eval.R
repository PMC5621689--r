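test_that("jackknife on a separable set is perfect and conserves counts", {
  d <- toy_blobs(60, sep = 6, seed = 81)
  ev <- jackknife_eval(d$x, d$y)
  expect_equal(ev$metrics$ACC, 1)
  expect_equal(ev$metrics$MCC, 1)
  m <- ev$metrics
  expect_equal(m$TP + m$TN + m$FP + m$FN, 60)
  expect_equal(nrow(ev$predictions), 60)
})

test_that("jackknife predictions equal a manual leave-one-out trace", {
  set.seed(82)
  x <- matrix(c(0, 0, 0.2, 0.1, 5, 5, 5.2, 4.9), ncol = 2, byrow = TRUE)
  y <- c(-1, -1, 1, 1)
  ev <- jackknife_eval(x, y)
  manual <- integer(4)
  for (i in 1:4) {
    fit <- train_svm(x[-i, ], y[-i])
    manual[i] <- predict(fit, x[i, , drop = FALSE])[1]
  }
  expect_equal(ev$predictions$pred, manual)
})

test_that("label-permuted data scores at chance over reseeds", {
  d <- toy_blobs(60, sep = 4, seed = 83)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    jackknife_eval(d$x, sample(d$y))$metrics$ACC
  }, 0)
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("swapping class labels swaps SN/SP and preserves ACC and |MCC|", {
  set.seed(84)
  x <- matrix(rnorm(80 * 3), 80)
  y <- rep(c(1, -1), 40)
  x[y == 1, 1] <- x[y == 1, 1] + 1.5
  a <- jackknife_eval(x, y)
  b <- jackknife_eval(x, -y)
  expect_equal(a$metrics$ACC, b$metrics$ACC)
  expect_equal(a$metrics$SN, b$metrics$SP)
  expect_equal(a$metrics$SP, b$metrics$SN)
  expect_equal(abs(a$metrics$MCC), abs(b$metrics$MCC))
})

test_that("stratified cross-validation is deterministic per seed", {
  set.seed(85)
  x <- matrix(rnorm(60 * 4), 60)
  y <- rep(c(1, -1), 30)
  x[y == 1, 1] <- x[y == 1, 1] + 2
  e1 <- cv_eval(x, y, seed = 7)
  e2 <- cv_eval(x, y, seed = 7)
  expect_identical(e1$predictions, e2$predictions)
  expect_error(jackknife_eval(x, rep(1, 60)), "both classes")
})

test_that("a one-value parameter grid reproduces the direct evaluation", {
  b <- gen_dataset(n_pos = 15, n_neg = 15, length_range = c(50, 80),
                   effect = 3, seed = 86)
  tab <- param_sweep("lg", grid = 10, records = b$records,
                     labels = b$labels, seed = 3)
  x <- encode_features(b$records, features = "nmbac", lg = 10)
  direct <- cv_eval(x, b$labels, seed = 3)
  expect_equal(tab$ACC, direct$metrics$ACC)
  expect_equal(attr(tab, "best"), 10)
  tab2 <- param_sweep("m", grid = c(20, 60), pssms = b$pssms,
                      labels = b$labels, seed = 3)
  expect_equal(tab2$value, c(20, 60))
  expect_true(all(tab2$ACC >= 0 & tab2$ACC <= 1))
  expect_identical(param_sweep("m", grid = c(20, 60), pssms = b$pssms,
                               labels = b$labels, seed = 3), tab2)
  expect_error(param_sweep("lg", grid = numeric(0), records = b$records,
                           labels = b$labels), "empty")
})

test_that("within-fold selection keeps the held-out sample out of ranking", {
  set.seed(87)
  n <- 40
  x <- matrix(rnorm(n * 30), n)
  y <- rep(c(1, -1), n / 2)
  x[y == 1, 1:2] <- x[y == 1, 1:2] + 2.5
  ev_in <- jackknife_eval(x, y, select_k = 5)
  ev_whole <- jackknife_eval(x, y, select_k = 5, selection = "whole")
  expect_equal(nrow(ev_in$predictions), n)
  expect_equal(nrow(ev_whole$predictions), n)
  # both find the strong signal here; the protocols just differ in bias
  expect_gte(ev_in$metrics$ACC, 0.8)
  expect_gte(ev_whole$metrics$ACC, 0.8)
})
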