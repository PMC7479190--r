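test_that("fluctuation measure hits its extreme cases", {
  r <- c(0, 1)
  expect_equal(fluctuation_measure(rep(0.4, 7), r), 0)
  expect_equal(fluctuation_measure(rep(c(0, 1), length.out = 7), r), 1)
  expect_equal(fluctuation_measure(seq(0, 1, length.out = 7), r), 1 / 36)
  expect_error(fluctuation_measure(1, r), "two points")
  # scale range applies after clipping
  expect_equal(fluctuation_measure(c(-5, 5, -5, 5, -5, 5, -5), r), 1)
})

test_that("distribution measure scores evenness of spread", {
  r <- c(0, 1)
  expect_equal(distribution_measure(seq(0, 1, length.out = 7), r), 1)
  expect_equal(distribution_measure(rep(0, 7), r), 0)
  # all values at mid-range: sum |0.5 - grid| = 2, denominator 3.5
  expect_equal(distribution_measure(rep(0.5, 7), r), 1 - 2 / 3.5)
  expect_error(distribution_measure(0.3, r), "two points")
})

test_that("dynamic complexity is zero for constants and bounded in [0,1]", {
  expect_equal(dynamic_complexity(pt_series(rep(2, 20)), range = c(0, 4))$values,
               rep(0, 14))
  expect_error(dynamic_complexity(pt_series(1:5)), "shorter")

  set.seed(8)
  for (rep_i in 1:25) {
    x <- switch(sample(3, 1),
                rnorm(40), runif(40, -2, 5), cumsum(rnorm(40)))
    dc <- dynamic_complexity(pt_series(x))
    expect_true(all(dc$values >= 0 & dc$values <= 1))
    expect_equal(dc$offset, 7L)
    expect_equal(length(dc$values), 34L)
  }
})

test_that("dynamic complexity is invariant under joint affine rescaling", {
  set.seed(9)
  x <- runif(60, 0, 10)
  a <- dynamic_complexity(pt_series(x), range = c(0, 10))
  b <- dynamic_complexity(pt_series(3 * x - 7), range = c(-7, 23))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("noise carries more dynamic complexity than a slow ramp", {
  set.seed(10)
  noise_dc <- replicate(30, {
    mean(dynamic_complexity(pt_series(runif(60)), range = c(0, 1))$values)
  })
  ramp_dc <- mean(dynamic_complexity(pt_series(seq(0, 1, length.out = 60)),
                                     range = c(0, 1))$values)
  expect_gt(mean(noise_dc), 5 * ramp_dc)
})

test_that("permutation entropy matches hand enumeration and its bounds", {
  expect_equal(permutation_entropy(pt_series(1:7))$values, 0)
  pe <- permutation_entropy(pt_series(c(1, 3, 2, 5, 4, 7, 6)))
  expect_equal(pe$values,
               -(0.6 * log(0.6) + 0.4 * log(0.4)) / log(6))
  expect_equal(pe$values, 0.3756, tolerance = 5e-4)
  # 8-point window whose six words realize all 6 ordinal patterns once
  all6 <- permutation_entropy(pt_series(c(7, 6, 1, 8, 3, 4, 5, 2)),
                              window = 8)
  expect_equal(all6$values, 1)
  expect_error(permutation_entropy(pt_series(1:10), window = 3, order = 3),
               "exceed")

  set.seed(12)
  for (rep_i in 1:25) {
    x <- sample(1:5, 40, replace = TRUE)  # coarse scale with many ties
    pe <- permutation_entropy(pt_series(x))
    expect_true(all(pe$values >= 0 & pe$values <= 1))
  }
})

test_that("permutation entropy is invariant under monotone transforms", {
  set.seed(13)
  x <- rnorm(50)
  a <- permutation_entropy(pt_series(x))$values
  expect_equal(permutation_entropy(pt_series(exp(x)))$values, a)
  expect_equal(permutation_entropy(pt_series(x^3 + 2 * x))$values, a)
})
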