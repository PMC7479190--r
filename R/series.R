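#' Time-series container
#'
#' A `pt_series` is an ordered sequence of real observations taken at a
#' constant sampling interval (e.g., one self-rating per day), with a label
#' and a 1-based first time index. It is the common currency of all
#' indicators in the package.
#'
#' @param values Numeric vector of observations; must be non-empty, finite,
#'   and free of missing values (missing-data handling is a pre-ingestion
#'   concern).
#' @param label Single character label for the series.
#' @param t0 Integer time index of the first observation (default 1).
#' @return An object of class `pt_series` with fields `values`, `label`,
#'   `t0`.
#' @examples
#' s <- pt_series(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4), label = "demo")
#' length(s$values)
#' @export
pt_series <- function(values, label = "x", t0 = 1L) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("a time series needs at least one observation", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series values must be finite and non-missing", call. = FALSE)
  stopifnot(is.character(label), length(label) == 1L)
  t0 <- as.integer(t0)
  structure(list(values = values, label = label, t0 = t0),
            class = "pt_series")
}

#' @export
print.pt_series <- function(x, ...) {
  cat(sprintf("<pt_series '%s'> n = %d, t0 = %d\n",
              x$label, length(x$values), x$t0))
  print(utils::head(x$values, 10L))
  invisible(x)
}

#' Multivariate time-series container
#'
#' A set of equally long, simultaneously sampled series (e.g., the items of
#' a questionnaire factor, or the component variables of a dynamical
#' system). Required by the synchronization indicator, which needs at least
#' two columns.
#'
#' @param columns A named list of numeric vectors, a data frame, or a
#'   numeric matrix with column names; all columns must have the same
#'   length and distinct labels.
#' @param t0 Integer time index of the first row (default 1).
#' @return An object of class `pt_multiseries` with fields `columns`
#'   (named list of numeric vectors), `labels`, `t0`.
#' @export
pt_multiseries <- function(columns, t0 = 1L) {
  if (is.matrix(columns)) columns <- as.data.frame(columns)
  if (is.data.frame(columns)) columns <- as.list(columns)
  if (!is.list(columns) || length(columns) < 1L)
    stop("columns must be a non-empty list, data frame, or matrix",
         call. = FALSE)
  labels <- names(columns)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("V", seq_along(columns))
  if (anyDuplicated(labels))
    stop("column labels must be distinct", call. = FALSE)
  columns <- lapply(columns, as.numeric)
  n <- unique(lengths(columns))
  if (length(n) != 1L)
    stop("all columns must have the same length", call. = FALSE)
  if (any(vapply(columns, function(v) anyNA(v) || any(!is.finite(v)),
                 logical(1))))
    stop("multiseries values must be finite and non-missing", call. = FALSE)
  names(columns) <- labels
  structure(list(columns = columns, labels = labels, t0 = as.integer(t0)),
            class = "pt_multiseries")
}

#' @export
print.pt_multiseries <- function(x, ...) {
  cat(sprintf("<pt_multiseries> %d columns x %d rows: %s\n",
              length(x$columns), length(x$columns[[1]]),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Derived indicator series
#'
#' The output of a moving-window indicator. Values live on a shorter time
#' axis than the source series; `offset` and `times` record the mapping
#' back to original time. All windowed indicators in the package use
#' trailing windows: the value computed from source points
#' `t - w + 1, ..., t` is assigned to time `t`, so `offset = t0 + w - 1`.
#' `times` may be irregular when individual points are undefined and have
#' been excluded (e.g., zero-power columns of a time-frequency matrix).
#'
#' @param values Numeric vector (may be empty).
#' @param window Integer window width `w >= 1` used to derive the values.
#' @param offset Original time index of the first derived value.
#' @param times Optional integer vector of original time indices, one per
#'   value; defaults to `offset, offset + 1, ...`.
#' @return An object of class `pt_derived`.
#' @export
pt_derived <- function(values, window, offset, times = NULL) {
  values <- as.numeric(values)
  window <- as.integer(window)
  offset <- as.integer(offset)
  stopifnot(window >= 1L)
  if (is.null(times)) times <- offset + seq_along(values) - 1L
  times <- as.integer(times)
  if (length(times) != length(values))
    stop("times must have one entry per value", call. = FALSE)
  structure(list(values = values, window = window, offset = offset,
                 times = times),
            class = "pt_derived")
}

#' @export
print.pt_derived <- function(x, ...) {
  cat(sprintf("<pt_derived> n = %d, window = %d, offset = %d\n",
              length(x$values), x$window, x$offset))
  print(utils::head(x$values, 10L))
  invisible(x)
}

series_values <- function(s) {
  if (inherits(s, "pt_series") || inherits(s, "pt_derived")) s$values
  else as.numeric(s)
}

series_t0 <- function(s) {
  if (inherits(s, "pt_series")) s$t0
  else if (inherits(s, "pt_derived")) s$offset
  else 1L
}

series_times <- function(s) {
  if (inherits(s, "pt_derived")) s$times
  else series_t0(s) + seq_along(series_values(s)) - 1L
}

#' z-transformation
#'
#' Standardizes a series to mean 0 and sample standard deviation 1, the
#' first step of the detection pipeline (all indicators and the penalized
#' change-point threshold assume comparable scales).
#'
#' @param s A `pt_series` (or numeric vector, coerced).
#' @return A `pt_series` of the same length and `t0`.
#' @examples
#' z <- z_transform(pt_series(c(2, 2, 2, 4, 4, 4, 4, 4, 4, 4)))
#' round(z$values[1], 3)  # (2 - 3.4) / 0.966
#' @export
z_transform <- function(s) {
  if (!inherits(s, "pt_series")) s <- pt_series(s)
  x <- s$values
  if (length(x) < 2L)
    stop("z-transform needs at least two observations", call. = FALSE)
  sdev <- stats::sd(x)
  if (sdev == 0)
    stop("cannot z-transform a constant (zero-variance) series",
         call. = FALSE)
  pt_series((x - mean(x)) / sdev, label = s$label, t0 = s$t0)
}

#' Moving average and moving variance
#'
#' Trailing-window smoothers used by the second-order change-point layer:
#' the mean (`moving_average`) or sample variance (`moving_variance`,
#' denominator `w - 1`) of each window of `w` consecutive values is
#' assigned to the window's last time point.
#'
#' @param s A `pt_series` or `pt_derived` (or numeric vector).
#' @param w Integer window width; `w >= 1` for the mean, `w >= 2` for the
#'   variance, and `w` must not exceed the series length.
#' @return A `pt_derived` of length `length(s) - w + 1` whose `offset` is
#'   the source's first time index plus `w - 1`.
#' @examples
#' moving_average(pt_series(1:4), 2)$values
#' @export
moving_average <- function(s, w) {
  x <- series_values(s)
  w <- as.integer(w)
  if (w < 1L) stop("window width must be >= 1", call. = FALSE)
  if (w > length(x))
    stop("window width exceeds series length", call. = FALSE)
  vals <- as.numeric(zoo::rollmean(x, k = w, align = "right"))
  derived_from(s, vals, w)
}

#' @rdname moving_average
#' @export
moving_variance <- function(s, w) {
  x <- series_values(s)
  w <- as.integer(w)
  if (w < 2L) stop("variance window must be >= 2", call. = FALSE)
  if (w > length(x))
    stop("window width exceeds series length", call. = FALSE)
  vals <- as.numeric(zoo::rollapply(zoo::zoo(x), width = w, FUN = stats::var,
                                    align = "right"))
  derived_from(s, vals, w)
}

# Chain a trailing-window derivation onto a series or an earlier derived
# series, keeping the time bookkeeping (possibly irregular `times`) intact:
# the derived value for window i is stamped with the time of the window's
# last source point.
derived_from <- function(s, vals, w) {
  times <- series_times(s)
  pt_derived(vals, window = w, offset = times[w],
             times = times[seq.int(w, length(times))])
}

#' Read a time series (or several) from CSV
#'
#' Reads a plain comma-separated file with one column per variable and one
#' row per time point. A header row is auto-detected (any non-numeric cell
#' in the first row). A column named `t`, `time`, or `index` holding the
#' consecutive time axis is dropped after setting `t0`.
#'
#' @param path Path to a CSV file; comma separator, `.` decimal.
#' @param column Optional column name or index to extract a single series.
#' @return A `pt_series` if the file (or `column` selection) has one data
#'   column, otherwise a `pt_multiseries`.
#' @export
read_series_csv <- function(path, column = NULL) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1L,
                           colClasses = "character",
                           strip.white = TRUE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header, strip.white = TRUE)
  if (!has_header) names(df) <- paste0("V", seq_along(df))
  t0 <- 1L
  tc <- which(tolower(names(df)) %in% c("t", "time", "index"))
  if (length(tc) == 1L) {
    tv <- df[[tc]]
    if (is.numeric(tv) && all(diff(tv) == 1)) t0 <- as.integer(tv[1])
    df <- df[-tc]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(df)[j], bad), call. = FALSE)
    }
  }
  if (!is.null(column)) df <- df[column]
  if (ncol(df) == 1L)
    pt_series(df[[1]], label = names(df)[1], t0 = t0)
  else
    pt_multiseries(df, t0 = t0)
}

#' Write a series to CSV
#'
#' @param s A `pt_series` or `pt_multiseries`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(s, path) {
  if (inherits(s, "pt_series")) {
    df <- stats::setNames(data.frame(s$values), s$label)
  } else if (inherits(s, "pt_multiseries")) {
    df <- as.data.frame(s$columns)
    names(df) <- s$labels
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
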