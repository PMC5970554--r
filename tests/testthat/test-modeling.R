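make_series <- function(n, seed = 1, noise = 0) {
  set.seed(seed)
  f <- runif(n, 1.8, 2.5)
  ref <- pmin(pmax(100 / (1 + exp(-8 * (f - 2.15))) + rnorm(n, sd = noise),
                   0), 100)
  data.frame(time_s = seq_len(n) * 5, feature = f, ref = ref)
}

test_that("splitting is exact, seeded and exhaustive", {
  s <- make_series(100)
  sp <- split_data(s, seed = 3)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$val), 15)
  expect_equal(nrow(sp$test), 15)
  all_rows <- sort(c(rownames(sp$train), rownames(sp$val), rownames(sp$test)))
  expect_equal(all_rows, sort(rownames(s)))
  sp2 <- split_data(s, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_data(s, fractions = c(1, 0, 0), seed = 1)
  expect_equal(nrow(sp3$train), 100)
  expect_equal(nrow(sp3$test), 0)
  expect_error(split_data(s[1:10, ]), "20")
  expect_error(split_data(s, fractions = c(0.5, 0.5, 0.5)), "fractions")
})

test_that("random forest recovers a noiseless monotone map in-sample", {
  x <- seq(1.5, 2.5, length.out = 200)
  y <- 100 / (1 + exp(-6 * (x - 2)))
  m <- fit_doa_model(data.frame(feature = x, ref = y), "rf",
                     hyperparams = list(nodesize = 5), seed = 1)
  expect_lt(mae(predict(m, x), y), 1)
})

test_that("every family predicts a constant target within 0.5", {
  set.seed(7)
  train <- data.frame(feature = rnorm(30) + 5, ref = rep(42, 30))
  newx <- rnorm(10) + 5
  for (fam in c("rf", "svm", "ann")) {
    m <- fit_doa_model(train, fam, seed = 2)
    expect_lt(max(abs(predict(m, newx) - 42)), 0.5)
  }
})

test_that("fits are deterministic given data and seed", {
  s <- make_series(120, seed = 4, noise = 5)
  sp <- split_data(s, seed = 1)
  newx <- seq(1.8, 2.5, length.out = 25)
  for (fam in c("rf", "svm", "ann")) {
    m1 <- fit_doa_model(sp$train, fam, seed = 11, val = sp$val)
    m2 <- fit_doa_model(sp$train, fam, seed = 11, val = sp$val)
    expect_identical(predict(m1, newx), predict(m2, newx))
  }
})

test_that("predictions are clipped to the index scale and empty input yields empty output", {
  s <- make_series(60, seed = 5, noise = 10)
  m <- fit_doa_model(s, "svm", seed = 1)
  p <- predict(m, seq(0, 5, length.out = 50))
  expect_true(all(p >= 0 & p <= 100))
  expect_identical(predict(m, numeric(0)), numeric(0))
  expect_error(fit_doa_model(s[1:5, ], "rf"), "10")
  expect_error(predict(m, data.frame(wrong = 1)), "feature")
})

test_that("training refuses non-finite feature rows", {
  s <- make_series(30)
  s$feature[3] <- NaN
  expect_error(fit_doa_model(s, "rf"), "non-finite")
})

test_that("the backprop network fits a smooth nonlinear relation", {
  set.seed(8)
  x <- runif(300, 1.5, 2.5)
  y <- 100 / (1 + exp(-6 * (x - 2)))
  sp <- split_data(data.frame(feature = x, ref = y), seed = 2)
  m <- fit_doa_model(sp$train, "ann", seed = 3, val = sp$val)
  expect_lt(mae(predict(m, sp$test$feature), sp$test$ref), 5)
})
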