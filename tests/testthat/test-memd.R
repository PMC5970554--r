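test_that("extrema detection matches the analytic count and a naive scan", {
  expect_equal(find_extrema(1:50), list(maxima = integer(0),
                                        minima = integer(0)))
  t <- (0:255) / 128 # two cycles of a 1 Hz tone
  e <- find_extrema(sin(2 * pi * t))
  expect_length(e$maxima, 2)
  expect_length(e$minima, 2)
  for (sd in 1:5) {
    set.seed(sd)
    x <- rnorm(100)
    expect_equal(find_extrema(x), oracle_extrema(x))
  }
})

test_that("plateau extrema contribute their midpoint index", {
  x <- c(0, 1, 5, 5, 5, 1, 0, -2, -2, 0)
  e <- find_extrema(x)
  expect_equal(e$maxima, 4L)  # midpoint of the 3-sample plateau at 3:5
  expect_equal(e$minima, 8L)  # midpoint of the 2-sample dip at 8:9
})

test_that("mean envelope is near zero for a pure tone and tracks a DC offset", {
  t <- (0:(5 * 128 - 1)) / 128
  x <- sin(2 * pi * 4 * t)
  interior <- seq(65, length(t) - 64)
  m <- envelope_mean(x)
  expect_lt(max(abs(m[interior])), 0.05)
  m2 <- envelope_mean(x + 2.5)
  expect_lt(max(abs(m2[interior] - 2.5)), 0.05)
})

test_that("the mean envelope respects the extremal bounds almost everywhere", {
  # cubic-spline envelopes can overshoot at isolated extrema; the bound
  # x >= mean envelope at maxima (and the reverse at minima) must hold at
  # 99% of interior extrema
  ok <- 0
  tot <- 0
  for (sd in 1:10) {
    set.seed(sd)
    x <- cumsum(rnorm(300)) # smooth-ish random walk
    m <- envelope_mean(x)
    e <- find_extrema(x)
    ok <- ok + sum(x[e$maxima] >= m[e$maxima] - 1e-9) +
      sum(x[e$minima] <= m[e$minima] + 1e-9)
    tot <- tot + length(e$maxima) + length(e$minima)
  }
  expect_gte(ok / tot, 0.99)
})

test_that("envelope mean signals too few extrema", {
  expect_null(envelope_mean(1:100))
})

test_that("EMD of a monotone ramp yields no IMFs", {
  d <- emd_decompose(seq(0, 1, length.out = 64))
  expect_length(d$imfs, 0)
  expect_equal(d$residual, seq(0, 1, length.out = 64))
})

test_that("EMD separates a 20 Hz + 2 Hz two-tone into its components", {
  tt <- two_tone()
  x <- tt$tone20 + tt$tone2
  d <- emd_decompose(x)
  expect_gte(length(d$imfs), 2)
  expect_gt(abs(cor(d$imfs[[1]], tt$tone20)), 0.95)
  expect_gt(abs(cor(d$imfs[[2]], tt$tone2)), 0.95)
})

test_that("EMD is complete to 1e-8 on random signals", {
  for (sd in 1:20) {
    set.seed(sd)
    x <- rnorm(400)
    expect_lt(completeness_err(x, emd_decompose(x)), 1e-8)
  }
})

test_that("extracted IMFs satisfy the extrema/zero-crossing property", {
  count_zc <- function(v) {
    s <- sign(v)
    s <- s[s != 0]
    sum(diff(s) != 0)
  }
  ok <- 0
  tot <- 0
  for (sd in 1:20) {
    set.seed(sd)
    d <- emd_decompose(rnorm(512))
    for (i in seq_len(max(0, length(d$imfs) - 1))) {
      e <- find_extrema(d$imfs[[i]])
      ne <- length(e$maxima) + length(e$minima)
      tot <- tot + 1
      if (abs(ne - count_zc(d$imfs[[i]])) <= 1) ok <- ok + 1
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("direction vectors are unit norm, deterministic and well spread in 2-D", {
  dv <- direction_vectors(64, 2, seed = 7)
  expect_equal(sqrt(rowSums(dv^2)), rep(1, 64), tolerance = 1e-12)
  expect_identical(dv, direction_vectors(64, 2, seed = 7))
  ang <- sort(atan2(dv[, 2], dv[, 1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_lt(max(gaps), 3 * (2 * pi / 64))

  dv3 <- direction_vectors(64, 3, seed = 1)
  expect_equal(sqrt(rowSums(dv3^2)), rep(1, 64), tolerance = 1e-12)
  expect_identical(dv3, direction_vectors(64, 3, seed = 1))
})

test_that("N-A-MEMD is complete on the data channel and deterministic under a fixed seed", {
  tt <- two_tone()
  x <- tt$tone20 + tt$tone2
  cfg <- memd_config(seed = 9)
  d1 <- na_memd_decompose(x, cfg)
  d2 <- na_memd_decompose(x, cfg)
  expect_identical(d1$imfs, d2$imfs)
  expect_identical(d1$residual, d2$residual)
  expect_lt(completeness_err(x, d1), 1e-6)
  d3 <- na_memd_decompose(x, memd_config(seed = 10))
  expect_false(identical(d1$imfs, d3$imfs))
})

test_that("a fully monotone multivariate signal yields no IMFs", {
  X <- cbind(seq(0, 1, length.out = 64), seq(2, 0, length.out = 64))
  dirs <- direction_vectors(8, 2, seed = 1)
  res <- doaEEG:::.cpp_memd(X, dirs, 8L, 100L, 0.2)
  expect_length(res[[1]]$imfs, 0)
  expect_equal(res[[1]]$residual, X[, 1])
})

test_that("noise assistance does not worsen two-tone mode mixing relative to plain EMD", {
  mm_na <- numeric(20)
  mm_emd <- numeric(20)
  for (sd in 1:20) {
    set.seed(sd)
    tt <- two_tone(phase20 = runif(1, 0, 2 * pi), phase2 = runif(1, 0, 2 * pi))
    x <- tt$tone20 + tt$tone2
    dn <- na_memd_decompose(x, memd_config(seed = sd))
    de <- emd_decompose(x)
    mm_na[sd] <- abs(cor(dn$imfs[[1]], tt$tone2))
    mm_emd[sd] <- abs(cor(de$imfs[[1]], tt$tone2))
  }
  expect_lte(mean(mm_na), mean(mm_emd) + 0.01)
  expect_lt(mean(mm_na), 0.1)
})

test_that("reconstruction sums exactly the selected IMFs and validates indices", {
  set.seed(3)
  d <- emd_decompose(rnorm(512))
  expect_gte(length(d$imfs), 3)
  full <- reconstruct(d, seq_along(d$imfs), include_residual = TRUE)
  set.seed(3)
  expect_equal(full, rnorm(512), tolerance = 1e-8)
  expect_equal(reconstruct(d, c(2, 3)), d$imfs[[2]] + d$imfs[[3]])
  expect_error(reconstruct(d, 99), "out of range")
  expect_error(reconstruct(d, integer(0)), "non-empty")
})

test_that("epoch-wise filtering preserves length, carries the mask and flags degenerate epochs", {
  fs <- 128
  set.seed(6)
  x <- rnorm(10 * fs)
  x[(5 * fs + 1):(10 * fs)] <- 0 # second half constant: no extrema
  rec <- eeg_record(x, fs = fs)
  f <- filter_epochwise(rec, window_spec(30, 5, 5))
  expect_length(f$samples, length(x))
  expect_false(any(f$artefact_mask[1:(5 * fs)]))
  expect_true(all(f$artefact_mask[(5 * fs + 1):(10 * fs)]))
  expect_true(all(f$samples[(5 * fs + 1):(10 * fs)] == 0))

  # trailing partial epoch passes through unfiltered but masked
  x2 <- rnorm(7.5 * fs)
  f2 <- filter_epochwise(eeg_record(x2, fs = fs), window_spec(30, 5, 5))
  tail_idx <- (5 * fs + 1):(7.5 * fs)
  expect_equal(f2$samples[tail_idx], x2[tail_idx])
  expect_true(all(f2$artefact_mask[tail_idx]))
})
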