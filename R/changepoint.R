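#' Change-point detection configuration
#'
#' @param k Nonnegative penalty (threshold) added to the two-segment cost;
#'   a split is accepted only if it lowers the cost by more than `k`. The
#'   default 1.0 is calibrated for z-scored input.
#' @param min_segment Minimum number of points per segment (default 2;
#'   variance is undefined on singletons).
#' @param statistic Which property shift to detect: `"mean"` (cost
#'   `N * var(x)`) or `"variance"` (cost `N * log(var(x))`).
#' @return A list of class `cpa_config`.
#' @export
cpa_config <- function(k = 1.0, min_segment = 2L,
                       statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  min_segment <- as.integer(min_segment)
  stopifnot(min_segment >= 2L)
  structure(list(k = k, min_segment = min_segment, statistic = statistic),
            class = "cpa_config")
}

#' Segment cost functions
#'
#' `cost_mean` is the cost used for mean-shift detection:
#' `C(x) = N * var(x)` with the sample variance (denominator `N - 1`);
#' a segment with fewer than two points costs 0. `cost_variance` is the
#' Gaussian log-likelihood cost for variance-shift detection:
#' `C(x) = N * log(max(var(x), 1e-12))`; segments are centered by their own
#' mean (implicit in the variance) and zero variance is clamped at 1e-12.
#'
#' @param x Numeric vector (a segment of a series).
#' @return A single cost value.
#' @examples
#' cost_mean(c(2, 4, 4, 4, 4, 4, 4, 4))     # 8 * 0.5 = 4
#' cost_mean(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4)) # 10 * 0.933 = 9.33
#' @export
cost_mean <- function(x) {
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  if (length(x) < 2L) return(0)
  length(x) * stats::var(x)
}

#' @rdname cost_mean
#' @export
cost_variance <- function(x) {
  if (length(x) < 2L)
    stop("variance cost needs at least two points", call. = FALSE)
  length(x) * log(max(stats::var(x), 1e-12))
}

# Vectorized segment costs for every admissible split of x, via cumulative
# sums. For split b (1-based first index of the right segment) the left
# segment is x[1..b-1] and the right x[b..N]. Returns left + right cost for
# each candidate b. Corrected sums-of-squares are clamped at zero to guard
# against cancellation.
split_costs <- function(x, bs, statistic) {
  n <- length(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  n1 <- bs - 1L
  n2 <- n - bs + 1L
  ss1 <- pmax(s2[n1] - s1[n1]^2 / n1, 0)
  ss2 <- pmax((s2[n] - s2[n1]) - (s1[n] - s1[n1])^2 / n2, 0)
  if (statistic == "mean") {
    c1 <- ifelse(n1 < 2L, 0, n1 * ss1 / (n1 - 1L))
    c2 <- ifelse(n2 < 2L, 0, n2 * ss2 / (n2 - 1L))
  } else {
    c1 <- n1 * log(pmax(ss1 / (n1 - 1L), 1e-12))
    c2 <- n2 * log(pmax(ss2 / (n2 - 1L), 1e-12))
  }
  c1 + c2
}

#' Detect a single change point
#'
#' Exhaustively evaluates every admissible split of the series into two
#' segments and accepts the best one if it beats the penalized cost of the
#' unsplit series: a change point exists at split `b` when
#' `C(x[1..b-1]) + C(x[b..N]) + k < C(x)`. The reported index is the first
#' point of the new (right) segment. Ties are broken toward the smallest
#' index.
#'
#' @param x Numeric vector, or a `pt_series`/`pt_derived` (values are
#'   used; index mapping to original time is the caller's concern).
#' @param cfg A [cpa_config()].
#' @return A one-row data frame with columns `index`, `statistic`,
#'   `cost_drop` (`C(x) - min split cost`), or `NULL` when no admissible
#'   split beats the penalty (including series shorter than
#'   `2 * min_segment`).
#' @examples
#' detect_single_change(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4))$index  # 4
#' @export
detect_single_change <- function(x, cfg = cpa_config()) {
  x <- series_values(x)
  n <- length(x)
  m <- cfg$min_segment
  if (n < 2L * m) return(NULL)
  bs <- seq.int(m + 1L, n - m + 1L)
  total <- split_costs(x, bs, cfg$statistic)
  full <- if (cfg$statistic == "mean") cost_mean(x) else cost_variance(x)
  i <- which.min(total)
  if (total[i] + cfg$k < full) {
    data.frame(index = bs[i], statistic = cfg$statistic,
               cost_drop = full - total[i])
  } else NULL
}

#' Detect one mean change and one variance change
#'
#' Runs [detect_single_change()] twice — once with the mean-shift cost and
#' once with the variance-shift cost — so a series can contribute at most
#' two change points, one per statistic.
#'
#' @param x Numeric vector or series object.
#' @param k Penalty threshold (default 1.0).
#' @param min_segment Minimum segment length (default 2).
#' @return A data frame with zero to two rows (`index`, `statistic`,
#'   `cost_drop`).
#' @export
detect_mean_and_variance <- function(x, k = 1.0, min_segment = 2L) {
  out <- rbind(
    detect_single_change(x, cpa_config(k, min_segment, "mean")),
    detect_single_change(x, cpa_config(k, min_segment, "variance"))
  )
  if (is.null(out))
    out <- data.frame(index = integer(0), statistic = character(0),
                      cost_drop = numeric(0))
  out
}
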