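test_that("z-transform standardizes, errors on constants, is idempotent", {
  s <- pt_series(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4))
  z <- z_transform(s)
  expect_equal(mean(z$values), 0)
  expect_equal(sd(z$values), 1)
  expect_equal(z$values[1], (2 - 3.4) / sd(s$values))
  expect_equal(z$values[1], -1.44913767, tolerance = 1e-6)
  expect_equal(length(z$values), 10L)
  expect_equal(z$t0, s$t0)

  expect_error(z_transform(pt_series(c(5, 5, 5))), "zero-variance")

  set.seed(7)
  r <- pt_series(rnorm(40, 3, 2))
  expect_equal(z_transform(z_transform(r))$values, z_transform(r)$values)
})

test_that("moving average and variance match brute force with offset bookkeeping", {
  ma <- moving_average(pt_series(1:4), 2)
  expect_equal(ma$values, c(1.5, 2.5, 3.5))
  expect_equal(ma$offset, 2L)

  expect_equal(moving_average(pt_series(rep(3, 9)), 4)$values, rep(3, 6))
  expect_equal(moving_average(pt_series(c(2, 7, 1)), 1)$values, c(2, 7, 1))
  expect_error(moving_average(pt_series(1:3), 4), "exceeds")

  expect_equal(moving_variance(pt_series(c(2, 4)), 2)$values, 2)
  expect_equal(moving_variance(pt_series(rep(1, 8)), 3)$values, rep(0, 6))

  set.seed(11)
  for (rep_i in 1:100) {
    n <- sample(25:60, 1)
    x <- rnorm(n)
    w <- sample(c(5L, 7L, 20L), 1)
    s <- pt_series(x, t0 = sample(1:5, 1))
    ma <- moving_average(s, w)
    mv <- moving_variance(s, w)
    expect_equal(ma$values, naive_rolling(x, w, mean), tolerance = 1e-12)
    expect_equal(mv$values, naive_rolling(x, w, var), tolerance = 1e-12)
    # derived position i corresponds to original time offset + i - 1
    expect_equal(ma$offset, s$t0 + w - 1L)
    expect_equal(ma$times, ma$offset + seq_along(ma$values) - 1L)
    expect_equal(length(ma$values), n - w + 1L)
  }
})

test_that("derived series chain through further windows keeps time mapping", {
  s <- pt_series(rnorm(50), t0 = 1L)
  d1 <- moving_average(s, 7)   # offset 7
  d2 <- moving_variance(d1, 5) # offset 11
  expect_equal(d2$offset, 11L)
  expect_equal(length(d2$values), 50 - 7 + 1 - 5 + 1)
  expect_equal(d2$times[1], 11L)
})

test_that("CSV round trips series and detects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(3)
  ms <- pt_multiseries(list(a = rnorm(80), b = rnorm(80), c = rnorm(80)))
  write_series_csv(ms, tmp)
  back <- read_series_csv(tmp)
  expect_s3_class(back, "pt_multiseries")
  expect_equal(length(back$columns), 3L)
  expect_equal(length(back$columns[[1]]), 80L)
  expect_equal(back$columns$a, ms$columns$a)
  expect_equal(back$labels, ms$labels)

  one <- read_series_csv(tmp, column = "b")
  expect_s3_class(one, "pt_series")
  expect_equal(one$label, "b")

  s <- pt_series(sin(1:30), label = "mood")
  write_series_csv(s, tmp)
  back1 <- read_series_csv(tmp)
  expect_s3_class(back1, "pt_series")
  expect_equal(back1$label, "mood")
  expect_equal(back1$values, s$values)

  writeLines(c("a,b", "1,2", "1,x", "3,4"), tmp)
  expect_error(read_series_csv(tmp), "row 2")

  # headerless numeric CSV and a consecutive time column
  writeLines(c("5,1.5", "6,2.5", "7,0.5"), tmp)
  plain <- read_series_csv(tmp)
  expect_s3_class(plain, "pt_multiseries")
  writeLines(c("time,y", "4,1.5", "5,2.5", "6,0.5"), tmp)
  timed <- read_series_csv(tmp)
  expect_s3_class(timed, "pt_series")
  expect_equal(timed$t0, 4L)
})

test_that("containers validate their invariants", {
  expect_error(pt_series(numeric(0)), "at least one")
  expect_error(pt_series(c(1, NA)), "finite")
  expect_error(pt_multiseries(list(a = 1:3, b = 1:4)), "same length")
  expect_error(pt_multiseries(list(a = 1:3, a = 4:6)), "distinct")
  expect_error(pt_derived(1:3, window = 2, offset = 2, times = 1:2),
               "one entry per value")
})
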