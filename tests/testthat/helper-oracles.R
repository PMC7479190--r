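# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths.

# naive single-split scan: all admissible splits, segment costs recomputed
# from scratch with stats::var
naive_detect <- function(x, statistic, k = 1, min_segment = 2L) {
  n <- length(x)
  if (n < 2L * min_segment) return(NULL)
  cost <- function(seg) {
    if (statistic == "mean") {
      if (length(seg) < 2L) 0 else length(seg) * stats::var(seg)
    } else {
      length(seg) * log(max(stats::var(seg), 1e-12))
    }
  }
  bs <- seq.int(min_segment + 1L, n - min_segment + 1L)
  tot <- vapply(bs, function(b) cost(x[1:(b - 1L)]) + cost(x[b:n]),
                numeric(1))
  i <- which.min(tot)
  full <- cost(x)
  if (tot[i] + k < full) list(index = bs[i], cost_drop = full - tot[i])
  else NULL
}

# brute-force trailing-window statistic
naive_rolling <- function(x, w, fun) {
  vapply(seq.int(w, length(x)), function(i) fun(x[(i - w + 1L):i]),
         numeric(1))
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a, b, tolerance = tol)
}
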