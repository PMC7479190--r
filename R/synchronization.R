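#' Synchronization pattern analysis
#'
#' Moving-window coherence of a multivariate system: within each trailing
#' window of `w` rows, the Pearson correlation of every pair of columns is
#' computed, absolute values are taken (synchronization is
#' sign-independent), and the `V * (V - 1) / 2` pair values are averaged.
#' Rising coherence among a system's components is an early-warning signal
#' of an approaching transition. Pairs in which either column is constant
#' within the window are excluded from the average; windows in which every
#' pair is excluded yield no value (the point is dropped, with time
#' bookkeeping preserved).
#'
#' @param ms A `pt_multiseries` with at least two columns.
#' @param window Window width (default 7); must be `>= 3` and no longer
#'   than the series.
#' @return A `pt_derived` with values in `[0, 1]`.
#' @export
spa <- function(ms, window = 7L) {
  if (!inherits(ms, "pt_multiseries"))
    stop("spa() needs a pt_multiseries", call. = FALSE)
  v <- length(ms$columns)
  if (v < 2L)
    stop("synchronization needs at least two columns", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L) stop("window must be >= 3", call. = FALSE)
  mat <- do.call(cbind, ms$columns)
  n <- nrow(mat)
  if (n < window) stop("series shorter than the window", call. = FALSE)
  idx <- seq.int(window, n)
  vals <- vapply(idx, function(i) {
    w <- mat[(i - window + 1L):i, , drop = FALSE]
    ok <- apply(w, 2L, stats::sd) > 0
    if (sum(ok) < 2L) return(NA_real_)
    r <- stats::cor(w[, ok, drop = FALSE])
    mean(abs(r[upper.tri(r)]))
  }, numeric(1))
  times <- (ms$t0 + seq_len(n) - 1L)[idx]
  keep <- !is.na(vals)
  pt_derived(vals[keep], window = window,
             offset = if (any(keep)) times[keep][1] else ms$t0 + window - 1L,
             times = times[keep])
}
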