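test_that("delay embedding follows its definition and count formula", {
  expect_equal(delay_embed(1:5, dim = 3, delay = 1),
               rbind(1:3, 2:4, 3:5))
  expect_equal(delay_embed(c(4, 2, 9), dim = 1, delay = 5),
               matrix(c(4, 2, 9), ncol = 1))
  set.seed(1)
  for (k in 1:10) {
    n <- sample(20:100, 1)
    dim <- sample(1:5, 1)
    delay <- sample(1:6, 1)
    if (n < (dim - 1) * delay + 1) next
    expect_equal(nrow(delay_embed(rnorm(n), dim, delay)),
                 n - (dim - 1) * delay)
  }
  expect_error(delay_embed(1:5, dim = 4, delay = 2), "short")
})

test_that("recurrence matrix saturates, isolates and matches pairwise distances", {
  set.seed(2)
  pts <- matrix(rnorm(30), ncol = 3)
  d <- as.matrix(dist(pts))
  expect_true(all(recurrence_matrix(pts, max(d) + 1)))
  iso <- recurrence_matrix(pts, min(d[d > 0]) / 2)
  expect_equal(unname(iso), diag(TRUE, nrow(pts)))
  R <- recurrence_matrix(pts, stats::median(d))
  for (i in 1:nrow(pts)) for (j in 1:nrow(pts)) {
    expect_equal(unname(R[i, j]), sqrt(sum((pts[i, ] - pts[j, ])^2)) <=
                   stats::median(d))
  }
})

test_that("recurrence rate counts off-diagonal density", {
  n <- 6
  expect_equal(recurrence_rate(matrix(TRUE, n, n)), 1)
  expect_equal(recurrence_rate(diag(TRUE, n)), 0)
  R <- diag(TRUE, n)
  R[1, 2] <- R[2, 1] <- R[3, 5] <- R[5, 3] <- R[2, 6] <- TRUE # 5 off-diag
  expect_equal(recurrence_rate(R), 5 / (6 * 5))
  expect_error(recurrence_rate(matrix(TRUE, 1, 1)), "square")
})

test_that("determinism matches the diagonal-run oracle and its conventions", {
  expect_equal(determinism(diag(TRUE, 5)), 0) # no off-diagonal points
  # all-true matrix: every off-diagonal point is on a line except the two
  # single-cell corner diagonals, which cannot reach lmin = 2
  expect_equal(determinism(matrix(TRUE, 5, 5)), 18 / 20)
  expect_equal(determinism(matrix(TRUE, 100, 100)), 1, tolerance = 1e-3)
  set.seed(3)
  for (k in 1:10) {
    R <- matrix(runif(144) < 0.3, 12, 12)
    R <- R | t(R)
    diag(R) <- TRUE
    expect_identical(determinism(R), oracle_det(R))
    expect_identical(determinism(R, lmin = 3), oracle_det(R, lmin = 3))
  }
})

test_that("a periodic trajectory is almost fully deterministic", {
  x <- sin(2 * pi * 4 * (0:639) / 128)
  pts <- delay_embed(x, 3, 5)
  R <- recurrence_matrix(pts, 0.1 * diff(range(x)))
  expect_gte(determinism(R), 0.95)
  expect_equal(determinism(R), oracle_det(R))
})

test_that("recurrence rate is monotone non-decreasing in the threshold", {
  set.seed(4)
  pts <- delay_embed(rnorm(200), 3, 5)
  rr <- vapply(seq(0.1, 3, by = 0.2),
               function(e) recurrence_rate(recurrence_matrix(pts, e)),
               numeric(1))
  expect_true(all(diff(rr) >= 0))
})

test_that("the compiled window path agrees with the matrix-based measures", {
  for (sd in 1:5) {
    set.seed(sd)
    x <- rnorm(300)
    p <- rqa_params(dim = 3, delay = 5, eps = 0.5, zscore = TRUE)
    fast <- rqa_features(x, p)
    z <- (x - mean(x)) / pop_sd_test(x)
    pts <- delay_embed(z, 3, 5)
    R <- recurrence_matrix(pts, 0.5)
    expect_equal(fast$rr, recurrence_rate(R), tolerance = 1e-12)
    expect_equal(fast$det, determinism(R), tolerance = 1e-12)
  }
})
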