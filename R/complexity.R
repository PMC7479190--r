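#' Fluctuation measure of a data window
#'
#' One half of the dynamic-complexity indicator. The window is partitioned
#' into maximal monotone runs (consecutive differences of equal sign); each
#' run contributes its absolute value change divided by its duration, and
#' the sum is normalized by the steepest signal the measurement scale
#' permits, `(hi - lo) * (m - 1)`. The result lies in `[0, 1]`: 0 for a
#' constant window, 1 for full-range alternation at every step. Values
#' outside the scale range are clipped to it.
#'
#' @param v Numeric window of length `m >= 2`.
#' @param range Length-2 numeric `c(lo, hi)` with `hi > lo`: the
#'   theoretical (rating scale) or observed bounds of the measurement.
#' @return A scalar in `[0, 1]`.
#' @examples
#' fluctuation_measure(rep(c(0, 1), length.out = 7), c(0, 1))  # 1
#' fluctuation_measure(seq(0, 1, length.out = 7), c(0, 1))     # 1/36
#' @export
fluctuation_measure <- function(v, range) {
  m <- length(v)
  if (m < 2L) stop("fluctuation needs at least two points", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("scale range must satisfy hi > lo", call. = FALSE)
  v <- pmin(pmax(v, lo), hi)
  d <- diff(v)
  sg <- sign(d)
  run_id <- cumsum(c(1L, sg[-1] != sg[-length(sg)]))
  dv <- abs(tapply(d, run_id, sum))
  dt <- tapply(rep(1L, length(d)), run_id, sum)
  sum(dv / dt) / ((hi - lo) * (m - 1))
}

#' Distribution measure of a data window
#'
#' The other half of dynamic complexity: how evenly the window's values
#' cover the measurement range. The sorted values are compared with an
#' ideal uniform grid from `lo` to `hi`; the summed deviation is scaled so
#' that the most degenerate window (all values at one end of the scale)
#' scores 0 and a perfectly even spread scores 1.
#'
#' @inheritParams fluctuation_measure
#' @return A scalar in `[0, 1]`.
#' @export
distribution_measure <- function(v, range) {
  m <- length(v)
  if (m < 2L) stop("distribution needs at least two points", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("scale range must satisfy hi > lo", call. = FALSE)
  v <- sort(pmin(pmax(v, lo), hi))
  grid <- lo + (seq_len(m) - 1) * (hi - lo) / (m - 1)
  max(0, 1 - sum(abs(v - grid)) / (m * (hi - lo) / 2))
}

#' Dynamic complexity
#'
#' A moving-window indicator of critical fluctuations designed for short,
#' coarse-grained rating time series: the product of the fluctuation
#' measure (amplitude and frequency of direction reversals) and the
#' distribution measure (evenness of value spread over the scale range),
#' computed in a trailing window. Elevated dynamic complexity before a
#' transition is an early-warning signal of critical instability.
#'
#' @param s A `pt_series` (or numeric vector).
#' @param window Window width (default 7, one week of daily ratings).
#' @param range Scale range `c(lo, hi)`; defaults to the observed global
#'   minimum and maximum of the series. Pass the nominal bounds of the
#'   rating scale when they are known.
#' @return A `pt_derived` with values in `[0, 1]`.
#' @export
dynamic_complexity <- function(s, window = 7L, range = NULL) {
  x <- series_values(s)
  window <- as.integer(window)
  if (window < 3L) stop("dynamic complexity needs window >= 3", call. = FALSE)
  if (length(x) < window)
    stop("series shorter than the window", call. = FALSE)
  if (is.null(range)) range <- c(min(x), max(x))
  if (!(range[2] > range[1]))
    stop("degenerate scale range (constant series?)", call. = FALSE)
  idx <- seq.int(window, length(x))
  vals <- vapply(idx, function(i) {
    w <- x[(i - window + 1L):i]
    fluctuation_measure(w, range) * distribution_measure(w, range)
  }, numeric(1))
  derived_from(s, vals, window)
}

# Ordinal pattern id of a word: ranks with ties broken by order of
# occurrence (earlier index gets the lower rank), collapsed to a string.
ordinal_pattern <- function(word) {
  paste(rank(word, ties.method = "first"), collapse = ".")
}

#' Permutation entropy
#'
#' Rank-based complexity of a series in a trailing moving window: every
#' run of `order` consecutive values ("word") inside the window is mapped
#' to its ordinal pattern (the permutation given by the ranks of its
#' values, ties broken by order of occurrence), and the Shannon entropy of
#' the pattern frequencies is normalized by `log(order!)` to `[0, 1]`.
#' Monotone windows score 0; windows visiting all patterns equally score 1.
#' Being rank-based, the indicator is invariant under strictly monotone
#' transformations of the values.
#'
#' @param s A `pt_series` (or numeric vector).
#' @param window Window width (default 7).
#' @param order Word length `n` (default 3), with `window > order`.
#' @return A `pt_derived` with values in `[0, 1]`.
#' @examples
#' # one window, hand-enumerable: patterns 1.3.2 (x3) and 2.1.3 (x2)
#' pe <- permutation_entropy(pt_series(c(1, 3, 2, 5, 4, 7, 6)))
#' round(pe$values, 4)  # 0.3756
#' @export
permutation_entropy <- function(s, window = 7L, order = 3L) {
  x <- series_values(s)
  window <- as.integer(window)
  order <- as.integer(order)
  if (window <= order)
    stop("window must exceed the word length", call. = FALSE)
  if (length(x) < window)
    stop("series shorter than the window", call. = FALSE)
  norm <- log(factorial(order))
  idx <- seq.int(window, length(x))
  vals <- vapply(idx, function(i) {
    w <- x[(i - window + 1L):i]
    words <- vapply(seq_len(window - order + 1L), function(j) {
      ordinal_pattern(w[j:(j + order - 1L)])
    }, character(1))
    p <- table(words) / length(words)
    -sum(p * log(p)) / norm
  }, numeric(1))
  derived_from(s, vals, window)
}
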