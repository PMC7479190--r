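test_that("segment costs reproduce the step-series walkthrough", {
  expect_equal(cost_mean(c(2, 2)), 0)
  expect_equal(cost_mean(c(2, 4, 4, 4, 4, 4, 4, 4)), 4)
  expect_equal(cost_mean(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4)), 9.3333333,
               tolerance = 1e-6)
  expect_error(cost_mean(numeric(0)), "empty")

  expect_equal(cost_variance(c(2, 4)), 2 * log(2))
  expect_equal(cost_variance(c(0, 0, 0, 0)), 4 * log(1e-12))
  expect_error(cost_variance(5), "two points")
  # shift invariance
  set.seed(4)
  x <- rnorm(30)
  expect_equal(cost_variance(x + 17.3), cost_variance(x))
})

test_that("single-split detection finds the step and respects the penalty", {
  cp <- detect_single_change(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4))
  expect_equal(cp$index, 4L)
  expect_equal(cp$statistic, "mean")
  expect_equal(cp$cost_drop, 9.3333333, tolerance = 1e-6)

  expect_null(detect_single_change(rep(1, 50)))
  expect_null(detect_single_change(c(1, 2, 3)))  # shorter than 2*min_segment
})

test_that("detection equals an exhaustive brute-force scan on random series", {
  set.seed(21)
  for (n in c(8, 20, 57, 120, 300)) {
    for (rep_i in 1:5) {
      x <- rnorm(n) + (runif(1) < 0.5) * c(rep(0, n %/% 2),
                                           rep(runif(1, 0, 2), n - n %/% 2))
      for (stat in c("mean", "variance")) {
        got <- detect_single_change(x, cpa_config(1, 2, stat))
        want <- naive_detect(x, stat, k = 1, min_segment = 2L)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$index, want$index)
          expect_equal(got$cost_drop, want$cost_drop, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("the set of detections can only shrink as the penalty grows", {
  set.seed(31)
  for (rep_i in 1:20) {
    x <- c(rnorm(40), rnorm(40, sample(0:2, 1), sample(1:3, 1)))
    ks <- c(0.5, 2, 8, 32, 128)
    counts <- vapply(ks, function(k) {
      nrow(detect_mean_and_variance(x, k = k))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # and a detection surviving a larger penalty is the same split
    for (i in seq_along(ks)[-1]) {
      hi <- detect_mean_and_variance(x, k = ks[i])
      lo <- detect_mean_and_variance(x, k = ks[i - 1])
      for (st in hi$statistic)
        expect_equal(hi$index[hi$statistic == st],
                     lo$index[lo$statistic == st])
    }
  }
})

test_that("mean and variance shifts are found near their true locations", {
  set.seed(5)
  # step in the mean only
  x <- c(rnorm(50, 0, 0.3), rnorm(50, 3, 0.3))
  cps <- detect_mean_and_variance(x)
  m <- cps[cps$statistic == "mean", ]
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$index - 51), 3)

  # step in the variance only
  y <- c(rnorm(100, 0, 1), rnorm(100, 0, 4))
  cps <- detect_mean_and_variance(y)
  v <- cps[cps$statistic == "variance", ]
  expect_equal(nrow(v), 1L)
  expect_lt(abs(v$index - 101), 6)

  expect_lte(nrow(detect_mean_and_variance(rnorm(60))), 2L)
})
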