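test_that("pearson correlation matches its closed form and flags constants", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cc(a, a), 1)
  expect_equal(pearson_cc(a, -a), -1)
  b <- c(2, 4, 5, 4, 5)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_cc(a, b), hand)
  expect_warning(cc <- pearson_cc(rep(1, 5), a), "constant")
  expect_true(is.nan(cc))
  expect_error(pearson_cc(1:3, 1:4), "length")
})

test_that("mean absolute error is symmetric and matches a naive loop", {
  expect_equal(mae(1:10, 1:10), 0)
  expect_equal(mae(1:10 + 5, 1:10), 5)
  set.seed(1)
  p <- runif(50, 0, 100)
  r <- runif(50, 0, 100)
  acc <- 0
  for (i in 1:50) acc <- acc + abs(p[i] - r[i])
  expect_equal(mae(p, r), acc / 50)
  expect_equal(mae(p, r), mae(r, p))
})

test_that("AUC handles perfect ranking, total ties and matches pair enumeration", {
  ref <- c(20, 30, 40, 50, 70, 80, 90, 95)
  expect_equal(auc_vs_reference(1:8, ref), 1)
  expect_equal(auc_vs_reference(rep(5, 8), ref), 0.5)
  set.seed(2)
  idx <- sample(1:5, 8, replace = TRUE)
  expect_equal(auc_vs_reference(idx, ref), oracle_auc(idx, ref))
  expect_error(auc_vs_reference(1:4, c(10, 20, 30, 40)), "classes")
})

test_that("AUC is invariant under strictly monotone transforms of the index", {
  set.seed(3)
  idx <- runif(40, 0, 100)
  ref <- runif(40, 0, 100)
  base <- auc_vs_reference(idx, ref)
  expect_equal(auc_vs_reference(exp(idx / 20), ref), base)
  expect_equal(auc_vs_reference(rank(idx), ref), base)
})

test_that("phase assignment uses upper-phase boundary ownership", {
  expect_equal(assign_phases(c(0, 39.9, 40, 50, 64.9, 65, 85, 99, 100)),
               c(1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L, 4L))
  expect_error(assign_phases(c(50, 101)), "0, 100")
})

test_that("phase distribution table is diagonal for identity and conserves counts", {
  set.seed(4)
  ref <- runif(80, 0, 100)
  pt <- phase_distribution_table(ref, ref)
  expect_equal(sum(diag(pt$counts)), 80)
  expect_true(all(pt$percent[pt$counts > 0] == 100 |
                    row(pt$counts)[pt$counts > 0] ==
                      col(pt$counts)[pt$counts > 0]))
  pred <- runif(80, 0, 100)
  pt2 <- phase_distribution_table(pred, ref)
  expect_equal(unname(rowSums(pt2$counts)), unname(pt2$n))
  expect_equal(sum(pt2$counts), 80)
})

test_that("a small phase table matches hand tabulation", {
  ref <- c(10, 20, 50, 50, 70, 90, 90, 95, 30, 60)
  pred <- c(15, 45, 55, 80, 70, 92, 60, 97, 20, 35)
  pt <- phase_distribution_table(pred, ref)
  hand <- matrix(c(2, 1, 0, 0,
                   1, 1, 1, 0,
                   0, 0, 1, 0,
                   0, 1, 0, 2), nrow = 4, byrow = TRUE)
  expect_equal(unname(pt$counts), hand)
})

test_that("ANOVA on ranks finds no differences under the null and all under strong separation", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- anova_on_ranks(g)
  expect_gt(res$p, 0.9)
  expect_false(any(res$pairwise$significant))

  set.seed(5)
  groups <- lapply(c(10, 30, 60, 90), function(mu) rnorm(50, mu, 2))
  res4 <- anova_on_ranks(groups)
  expect_lt(res4$p, 1e-10)
  expect_true(all(res4$pairwise$significant))
  # H agrees with the textbook rank formula (tie-free data)
  N <- 200
  rk <- rank(unlist(groups))
  rbar <- tapply(rk, rep(1:4, each = 50), mean)
  H_hand <- 12 / (N * (N + 1)) * sum(50 * (rbar - (N + 1) / 2)^2)
  expect_equal(res4$H, H_hand, tolerance = 1e-9)

  expect_error(anova_on_ranks(list(1:5)), "2 groups")
  expect_error(anova_on_ranks(list(1:5, 3)), "at least 2 values")
})

test_that("SNK blocking declares inner pairs non-significant when a range fails", {
  set.seed(6)
  # two clearly separated clusters; the two groups inside each cluster equal
  g <- list(rnorm(30, 10, 1), rnorm(30, 10, 1),
            rnorm(30, 90, 1), rnorm(30, 90, 1))
  res <- anova_on_ranks(g)
  pw <- res$pairwise
  sig_span2 <- pw$significant[pw$span == 2]
  # adjacent pairs inside a cluster must not be significant
  expect_false(all(sig_span2))
  # the extreme pair must be significant
  expect_true(pw$significant[pw$span == 4])
})

test_that("session evaluation bundles the battery and behaves on identity and shuffles", {
  set.seed(7)
  ref <- runif(120, 0, 100)
  rep_id <- evaluate_session(ref, ref)
  expect_equal(rep_id$cc, 1)
  expect_equal(rep_id$mae, 0)
  expect_equal(rep_id$auc, 1)
  expect_equal(sum(diag(rep_id$phase_table$counts)), 120)

  aucs <- vapply(1:20, function(sd) {
    set.seed(sd)
    evaluate_session(sample(ref), ref)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_true(all(abs(aucs - 0.5) < 0.2))
})
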