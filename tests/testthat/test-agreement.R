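test_that("percentage differences follow the reference-denominator formula", {
  expect_equal(percent_difference(c(3, 4), c(3, 4))$per_pair, c(0, 0))
  expect_equal(percent_difference(11, 10)$per_pair, 10)
  pd <- percent_difference(c(10.1, 9.5), c(10, 10))
  expect_equal(pd$per_pair, c(1, -5))
  expect_equal(pd$mean_pct, -2)
  expect_equal(pd$largest_pct, -5)   # largest magnitude, sign preserved
  expect_error(percent_difference(1, 0), "zeros")
  expect_error(percent_difference(1:3, 1:2), "equal length")
})

test_that("agreement analysis satisfies its exact identities", {
  b <- c(8.2, 10.1, 12.7, 14.9, 9.4)
  r_same <- agreement_analysis(b, b)
  expect_equal(r_same$slope, 1)
  expect_equal(r_same$intercept, 0, tolerance = 1e-12)
  expect_equal(r_same$pearson_r, 1)
  expect_equal(r_same$bias, 0)
  expect_equal(c(r_same$loa_low, r_same$loa_high), c(0, 0))
  r_twice <- agreement_analysis(2 * b, b)
  expect_equal(r_twice$slope, 2)
  expect_equal(r_twice$pearson_r, 1)
  expect_error(agreement_analysis(b, rep(1, 5)), "zero variance")
  expect_error(agreement_analysis(1:2, 1:2), ">= 3")
})

test_that("agreement analysis matches independent brute-force formulas", {
  a <- c(1, 2, 3, 4)
  b <- c(1.1, 1.9, 3.2, 3.8)
  rep <- agreement_analysis(a, b)
  # Pearson r from the raw sum formulas
  n <- 4
  r_hand <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  expect_equal(rep$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(rep$r_squared, r_hand^2, tolerance = 1e-12)
  # OLS slope/intercept from the normal equations
  slope_hand <- (n * sum(a * b) - sum(a) * sum(b)) /
    (n * sum(b^2) - sum(b)^2)
  expect_equal(rep$slope, slope_hand, tolerance = 1e-12)
  expect_equal(rep$intercept, mean(a) - slope_hand * mean(b),
               tolerance = 1e-12)
  # Bland-Altman from the definition (sample SD, n - 1)
  d <- a - b
  sd_hand <- sqrt(sum((d - mean(d))^2) / (n - 1))
  expect_equal(rep$bias, mean(d))
  expect_equal(rep$loa_low, mean(d) - 1.96 * sd_hand, tolerance = 1e-12)
  expect_equal(rep$loa_high, mean(d) + 1.96 * sd_hand, tolerance = 1e-12)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
})

test_that("agreement invariances hold on random data", {
  set.seed(21)
  for (i in 1:5) {
    a <- stats::rnorm(20, 14, 2)
    b <- a + stats::rnorm(20, 0, 0.5)
    r0 <- agreement_analysis(a, b)
    # Pearson r invariant under affine rescaling of either argument
    r1 <- agreement_analysis(3 * a - 7, b)
    r2 <- agreement_analysis(a, 0.5 * b + 2)
    expect_equal(r1$pearson_r, r0$pearson_r, tolerance = 1e-12)
    expect_equal(r2$pearson_r, r0$pearson_r, tolerance = 1e-12)
    # Bland-Altman bias is antisymmetric under swapping the series
    r_sw <- agreement_analysis(b, a)
    expect_equal(r_sw$bias, -r0$bias, tolerance = 1e-12)
  }
})
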