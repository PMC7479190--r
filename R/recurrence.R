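#' Time-delay embedding
#'
#' Reconstructs state vectors from a scalar series: vector `i` is
#' `(x[i], x[i + delay], ..., x[i + (dimension - 1) * delay])`, giving
#' `N - (dimension - 1) * delay` vectors.
#'
#' @param s A `pt_series` (or numeric vector).
#' @param dimension Embedding dimension `d >= 1` (default 3).
#' @param delay Time delay `tau >= 1` (default 1).
#' @return A numeric matrix with one embedded vector per row.
#' @export
embed_series <- function(s, dimension = 3L, delay = 1L) {
  x <- series_values(s)
  dimension <- as.integer(dimension)
  delay <- as.integer(delay)
  stopifnot(dimension >= 1L, delay >= 1L)
  m <- length(x) - (dimension - 1L) * delay
  if (m < 1L)
    stop("series too short for this embedding", call. = FALSE)
  cols <- vapply(seq_len(dimension), function(j) {
    x[seq.int((j - 1L) * delay + 1L, length.out = m)]
  }, numeric(m))
  matrix(cols, nrow = m, ncol = dimension)
}

#' Recurrence distance matrix
#'
#' Pairwise Euclidean distances between time-delay-embedded state vectors:
#' the unthresholded (distance-coded) recurrence plot. Low distances mark
#' times when the system revisits an earlier pattern; a change of the
#' dynamical regime shows up as a block structure.
#'
#' @param s A `pt_series` (or numeric vector), or a numeric matrix of
#'   already-embedded vectors (one per row).
#' @param dimension,delay Embedding parameters, used when `s` is a series.
#' @param t0 First original time index (taken from `s` when it is a
#'   series).
#' @return An object of class `recurrence_matrix`: list with `distances`
#'   (symmetric M x M matrix, zero diagonal), `dimension`, `delay`, and
#'   `times` (the original time index assigned to each embedded vector —
#'   the last point it covers, consistent with the trailing-window
#'   convention of the other indicators).
#' @export
recurrence_matrix <- function(s, dimension = 3L, delay = 1L, t0 = NULL) {
  if (is.matrix(s)) {
    vectors <- s
    if (is.null(t0)) t0 <- 1L
    span <- (dimension - 1L) * delay
  } else {
    if (is.null(t0)) t0 <- series_t0(s)
    vectors <- embed_series(s, dimension, delay)
    span <- (dimension - 1L) * delay
  }
  if (nrow(vectors) < 2L)
    stop("need at least two embedded vectors", call. = FALSE)
  d <- as.matrix(stats::dist(vectors))
  dimnames(d) <- NULL
  structure(list(distances = d,
                 dimension = as.integer(dimension),
                 delay = as.integer(delay),
                 times = as.integer(t0) + span + seq_len(nrow(d)) - 1L),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d (d = %d, tau = %d)\n",
              nrow(x$distances), ncol(x$distances), x$dimension, x$delay))
  invisible(x)
}

#' Write a recurrence matrix to CSV
#'
#' @param m A `recurrence_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_recurrence_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$distances), path, row.names = FALSE)
  invisible(path)
}

#' Change points of a recurrence plot
#'
#' Quantifies the transition structure of a recurrence plot by running
#' mean- and variance-shift change-point detection on every row of the
#' distance matrix and pooling: the change point of the whole plot (per
#' statistic) is the arithmetic mean of the row-wise detections, rounded
#' to the nearest integer and mapped to original time. Rows with no
#' detection are skipped (not counted as zeros); a statistic with no
#' detections in any row contributes no change point. Each row is z-scored
#' before detection so the penalty acts on a comparable scale; constant
#' rows are skipped.
#'
#' @param m A `recurrence_matrix`, or a plain (distance) matrix, in which
#'   case column `j` is taken to be original time `j`.
#' @param k Penalty threshold for the row-wise detector; `NULL` (default)
#'   uses the length-adaptive `2 * log(M)` for rows of `M` points.
#' @param min_segment Minimum segment length (default 2).
#' @param rescale If `TRUE` (default) each row is z-scored before
#'   detection so the penalty acts on a comparable scale.
#' @return A data frame with zero to two rows: `time` (original index),
#'   `statistic`, and `n_rows` (how many matrix rows contributed).
#' @export
rp_changepoints <- function(m, k = NULL, min_segment = 2L, rescale = TRUE) {
  if (is.matrix(m))
    m <- structure(list(distances = m, dimension = 1L, delay = 1L,
                        times = seq_len(nrow(m))),
                   class = "recurrence_matrix")
  rows <- m$distances
  if (is.null(k)) k <- 2 * log(ncol(rows))
  hits <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    s <- stats::sd(r)
    if (s == 0) return(NULL)
    if (rescale) r <- (r - mean(r)) / s
    detect_mean_and_variance(r, k = k, min_segment = min_segment)
  })
  hits <- do.call(rbind, hits)
  out <- data.frame(time = integer(0), statistic = character(0),
                    n_rows = integer(0))
  if (is.null(hits) || nrow(hits) == 0L) return(out)
  for (stat in c("mean", "variance")) {
    idx <- hits$index[hits$statistic == stat]
    if (length(idx) > 0L) {
      pooled <- as.integer(round(mean(idx)))
      out <- rbind(out, data.frame(time = m$times[pooled], statistic = stat,
                                   n_rows = length(idx)))
    }
  }
  out
}
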