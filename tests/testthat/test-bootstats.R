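test_that("identical constant groups give p = 1 and zero statistic", {
  cfg <- bootstrap_config(B_test = 200, seed = 4)
  r <- bootstrap_median_test(c(5, 5, 5, 5), c(5, 5, 5, 5), cfg)
  expect_equal(r$observed_stat, 0)
  expect_equal(r$p_raw, 1)
})

test_that("2+2 bootstrap p matches the exhaustive pooled-resample oracle", {
  a <- c(0, 1)
  b <- c(10, 11)
  pool <- c(a, b)
  # oracle: enumerate all 4^4 equally likely pooled resamples
  t_obs <- abs(median(a) - median(b))
  grid <- expand.grid(i1 = 1:4, i2 = 1:4, i3 = 1:4, i4 = 1:4)
  t_star <- apply(grid, 1, function(ix) {
    v <- pool[ix]
    abs(median(v[1:2]) - median(v[3:4]))
  })
  p_exact <- mean(t_star >= t_obs)
  B <- 10000L
  r <- bootstrap_median_test(a, b, bootstrap_config(B_test = B, seed = 7))
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(r$p_raw - p_exact), 3 * mc_se)
})

test_that("a huge separation yields a tiny p", {
  set.seed(99)
  a <- rnorm(1000)
  b <- rnorm(1000, mean = 10)
  r <- bootstrap_median_test(a, b, bootstrap_config(B_test = 2000, seed = 1))
  expect_lte(r$p_raw, 0.001)
})

test_that("tests are seed-deterministic and exchangeable within groups", {
  set.seed(3)
  a <- rnorm(12)
  b <- rnorm(15, 0.4)
  cfg <- bootstrap_config(B_test = 500, seed = 21)
  r1 <- bootstrap_median_test(a, b, cfg, "E", "C")
  r2 <- bootstrap_median_test(a, b, cfg, "E", "C")
  expect_identical(r1$p_raw, r2$p_raw)
  r3 <- bootstrap_median_test(sample(a), rev(b), cfg, "E", "C")
  expect_identical(r1$p_raw, r3$p_raw)
  # different labels use a different substream
  r4 <- bootstrap_median_test(a, b, cfg, "E2", "C")
  expect_false(identical(r1$seed, r4$seed))
})

test_that("plus-one estimator floors p at 1/(B+1); plain estimator can hit 0", {
  a <- c(0, 0.1, 0.2)
  b <- c(100, 100.1, 100.2)
  r <- bootstrap_median_test(a, b, bootstrap_config(B_test = 50, seed = 2,
                                                    plus_one = TRUE))
  expect_gte(r$p_raw, 1 / 51)
  expect_error(bootstrap_median_test(c(1), c(1, 2), bootstrap_config()),
               ">= 2")
  expect_error(bootstrap_median_test(c(1, NA, 2), c(1, 2),
                                     bootstrap_config()), "missing")
})

test_that("BH and Hochberg adjustments match hand step-up oracles", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(0.04, 5), "BH"), rep(0.04, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # naive step-up oracles for m <= 10 hypotheses
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  hochberg_oracle <- function(p) {
    # step-up from the largest p: the k-th largest is multiplied by k
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- cummin(seq_len(m) * p[o])
    pmin(adj, 1)[order(o)]
  }
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(2:10, 1))
    expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p))
    expect_equal(adjust_pvalues(p, "hochberg"), hochberg_oracle(p))
    # monotone: adjusted >= raw, order preserved
    expect_true(all(adjust_pvalues(p, "BH") >= p))
  }
})

test_that("percentile median CI: degenerate, oracle and equivariance cases", {
  cfg <- bootstrap_config(B_ci = 300, seed = 5)
  ci <- bootstrap_median_ci(rep(4.2, 10), cfg)
  expect_equal(unname(ci), c(4.2, 4.2))
  set.seed(14)
  x <- rnorm(20)
  ci1 <- bootstrap_median_ci(x, cfg, label = "v")
  # brute-force resampler with the same derived substream and percentile rule
  oracle <- withr::with_seed(vamrbiome:::derive_seed(5L, "ci", "v"), {
    xs <- sort(x)   # resampling is defined on the order statistics
    draws <- matrix(xs[sample.int(20, 20 * 300, replace = TRUE)], nrow = 20)
    meds <- apply(draws, 2, median)
    quantile(meds, c(0.025, 0.975), names = FALSE)
  })
  expect_equal(unname(ci1), oracle)
  expect_lte(ci1["lower"], ci1["upper"])
  ci2 <- bootstrap_median_ci(x + 3, cfg, label = "v")
  expect_equal(unname(ci2), unname(ci1) + 3)
  expect_error(bootstrap_median_ci(numeric(0), cfg), ">= 2")
})

test_that("endpoint test family enumerates endpoints x comparisons", {
  set.seed(31)
  groups <- paste0("g", 1:6)
  tab <- tibble::tibble(
    well_id = paste0("w", 1:60),
    group = rep(groups, each = 10))
  for (ep in endpoint_names()) tab[[ep]] <- rlnorm(60)
  cfg <- bootstrap_config(B_test = 50, seed = 9)
  res <- run_endpoint_tests(tab, control = "g1", config = cfg)
  expect_identical(nrow(res), 125L)
  expect_identical(length(unique(res$endpoint)), 25L)
  expect_identical(length(unique(res$comparison)), 5L)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_error(run_endpoint_tests(tab, control = "nope", config = cfg),
               "control")
  # determinism of the whole family
  res2 <- run_endpoint_tests(tab, control = "g1", config = cfg)
  expect_identical(res$p_raw, res2$p_raw)
})

test_that("median CI series covers each time bin", {
  act <- tibble::tibble(
    well_id = rep(paste0("w", 1:8), times = 3),
    time_s = rep(0:2, each = 8),
    activity = rep(c(1, 2, 3), each = 8) + rep(seq(0, 0.7, 0.1), 3))
  ser <- median_ci_series(act, bootstrap_config(B_ci = 100, seed = 2))
  expect_identical(nrow(ser), 3L)
  expect_true(all(ser$lower <= ser$median & ser$median <= ser$upper))
})
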