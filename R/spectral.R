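#' Stockwell time-frequency transform
#'
#' Computes the discrete S-transform of a series via its frequency-domain
#' formulation: the signal's DFT is shifted to each voice (frequency bin)
#' `n = 1..floor(N/2)`, windowed with a frequency-scaled Gaussian
#' `exp(-2 * pi^2 * m^2 / n^2)` (with `m` the circularly wrapped frequency
#' offset), and inverse-transformed over time. The S-transform combines
#' the absolutely referenced phase of the short-time Fourier transform
#' with the frequency-adaptive window of the continuous wavelet transform,
#' making it suited to localizing frequency changes in non-stationary
#' signals. The series mean is removed before transforming; the
#' zero-frequency row carries that mean's magnitude.
#'
#' @param s A `pt_series` (or numeric vector) of length `N >= 8`.
#' @return An object of class `stockwell_tfd`: a list with `amplitude`
#'   (nonnegative matrix, one row per frequency from 0 up to 0.5
#'   cycles/sample, one column per time point), `freqs` (cycles/sample),
#'   and `times` (original time indices).
#' @export
stockwell_transform <- function(s) {
  x <- series_values(s)
  n_len <- length(x)
  if (n_len < 8L) stop("S-transform needs at least 8 points", call. = FALSE)
  mu <- mean(x)
  X <- stats::fft(x - mu)
  nv <- n_len %/% 2L
  m <- 0:(n_len - 1L)
  mw <- ifelse(m > n_len / 2, m - n_len, m)  # wrapped frequency offsets
  amp <- matrix(0, nrow = nv + 1L, ncol = n_len)
  amp[1L, ] <- abs(mu)
  for (v in seq_len(nv)) {
    shifted <- X[(m + v) %% n_len + 1L]
    g <- exp(-2 * pi^2 * mw^2 / v^2)
    row <- stats::fft(shifted * g, inverse = TRUE) / n_len
    amp[v + 1L, ] <- Mod(row)
  }
  structure(list(amplitude = amp,
                 freqs = c(0, seq_len(nv)) / n_len,
                 times = series_times(s)),
            class = "stockwell_tfd")
}

#' @export
print.stockwell_tfd <- function(x, ...) {
  cat(sprintf("<stockwell_tfd> %d frequencies x %d time points\n",
              nrow(x$amplitude), ncol(x$amplitude)))
  invisible(x)
}

#' Write a time-frequency matrix to CSV for inspection
#'
#' @param tfd A `stockwell_tfd`.
#' @param path Output path; rows are frequencies (first column `freq`),
#'   remaining columns the time points.
#' @return The path, invisibly.
#' @export
write_tfd_csv <- function(tfd, path) {
  df <- data.frame(freq = tfd$freqs, tfd$amplitude)
  names(df)[-1] <- paste0("t", tfd$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Instantaneous frequency
#'
#' Reduces a time-frequency distribution to one series: the first
#' conditional spectral moment, i.e. the power-weighted mean frequency at
#' each time point, `IF(t) = sum(f * P(t, f)) / sum(P(t, f))` with
#' `P = amplitude^2`. The zero-frequency voice is excluded from the
#' moment. Time points whose spectral power is entirely zero are undefined
#' and dropped (the `times` field of the result keeps the mapping back to
#' original time).
#'
#' @param tfd A `stockwell_tfd` from [stockwell_transform()].
#' @return A `pt_derived` with values in `[0, 0.5]` cycles/sample.
#' @export
instantaneous_frequency <- function(tfd) {
  pw <- tfd$amplitude[-1L, , drop = FALSE]^2
  f <- tfd$freqs[-1L]
  tot <- colSums(pw)
  if (all(tot == 0))
    stop("time-frequency distribution has no power", call. = FALSE)
  keep <- tot > 0
  vals <- colSums(pw[, keep, drop = FALSE] * f) / tot[keep]
  pt_derived(vals, window = 1L, offset = tfd$times[1],
             times = tfd$times[keep])
}
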