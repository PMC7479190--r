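test_that("S-transform localizes stationary and switching sinusoids", {
  expect_error(stockwell_transform(pt_series(1:5)), "at least 8")

  tfd0 <- stockwell_transform(pt_series(rep(0, 32)))
  expect_true(all(tfd0$amplitude == 0))

  n <- 256
  s <- pt_series(sin(2 * pi * 0.1 * seq_len(n)))
  tfd <- stockwell_transform(s)
  expect_true(all(tfd$amplitude >= 0))
  expect_equal(nrow(tfd$amplitude), n %/% 2 + 1L)
  expect_true(all(diff(tfd$freqs) > 0))
  ridge <- apply(tfd$amplitude[, 30:226], 2, which.max)
  expect_true(all(abs(tfd$freqs[ridge] - 0.1) <= 1 / n + 1e-9))

  # frequency switch mid-series: ridge follows within +-5 samples
  x <- c(sin(2 * pi * 0.05 * 1:128), sin(2 * pi * 0.2 * 129:256))
  tfd2 <- stockwell_transform(pt_series(x))
  ridge2 <- tfd2$freqs[apply(tfd2$amplitude, 2, which.max)]
  switch_at <- which(ridge2[20:236] > 0.125)[1] + 19L
  expect_lt(abs(switch_at - 129), 6)
})

test_that("instantaneous frequency is the power-weighted mean frequency", {
  n <- 256
  tfd <- stockwell_transform(pt_series(sin(2 * pi * 0.1 * seq_len(n))))
  iff <- instantaneous_frequency(tfd)
  expect_equal(length(iff$values), n)
  expect_true(all(iff$values >= 0 & iff$values <= 0.5))
  expect_lt(max(abs(iff$values[40:216] - 0.1)), 0.02)

  expect_error(instantaneous_frequency(
    stockwell_transform(pt_series(rep(0, 32)))), "no power")
})

test_that("IF of a frequency-shifted sinusoid shifts by the same amount", {
  n <- 256
  t <- seq_len(n)
  base <- sapply(c(0.05, 0.10, 0.20), function(f) {
    iff <- instantaneous_frequency(stockwell_transform(pt_series(sin(2 * pi * f * t))))
    mean(iff$values[40:216])
  })
  expect_lt(abs(base[2] - base[1] - 0.05), 0.015)
  expect_lt(abs(base[3] - base[1] - 0.15), 0.015)
})

test_that("white-noise IF is stable above the flat-spectrum midpoint", {
  # the S-transform's analysis bandwidth grows with frequency, so under a
  # flat input spectrum the power-weighted mean frequency sits above the
  # naive midpoint 0.25; the reference value is a Monte-Carlo estimate
  set.seed(14)
  ifs <- replicate(100, {
    iff <- instantaneous_frequency(stockwell_transform(pt_series(rnorm(64))))
    mean(iff$values)
  })
  expect_gt(mean(ifs), 0.25)
  expect_lt(abs(mean(ifs) - 0.316), 0.03)
})

test_that("total TFD power grows with series variance", {
  set.seed(15)
  sds <- runif(20, 0.2, 5)
  pw <- vapply(sds, function(s) {
    sum(stockwell_transform(pt_series(rnorm(48, 0, s)))$amplitude^2)
  }, numeric(1))
  expect_gt(cor(sds^2, pw, method = "spearman"), 0.9)
})

test_that("a mid-series frequency switch is caught by the change-point layer", {
  x <- c(sin(2 * pi * 0.05 * 1:150), sin(2 * pi * 0.2 * 151:300)) +
    rnorm(300, 0, 0.05)
  set.seed(16)
  iff <- instantaneous_frequency(stockwell_transform(z_transform(pt_series(x))))
  v <- iff$values
  cps <- detect_mean_and_variance((v - mean(v)) / sd(v),
                                  k = 2 * log(length(v)))
  m <- cps[cps$statistic == "mean", ]
  expect_equal(nrow(m), 1L)
  expect_lt(abs(iff$times[m$index] - 151), 12)
})
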