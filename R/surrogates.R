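#' Surrogate test configuration
#'
#' @param n_sets Number of random surrogate change-point sets (default
#'   100).
#' @param seed Optional integer seed; when given, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @param ci_level Coverage of the percentile confidence interval over the
#'   surrogate statistics (default 0.95).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   for the IQR and the CI bounds (default 7, linear interpolation of
#'   order statistics).
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_sets = 100L, seed = NULL, ci_level = 0.95,
                             quantile_type = 7L) {
  n_sets <- as.integer(n_sets)
  stopifnot(n_sets >= 2L, ci_level > 0, ci_level < 1)
  structure(list(n_sets = n_sets, seed = seed, ci_level = ci_level,
                 quantile_type = as.integer(quantile_type)),
            class = "surrogate_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw uniform random change-point sets
#'
#' Draws `n_sets` independent sets of `n_points` integers, each uniform on
#' `{1, ..., N}` (with replacement, so duplicates can occur, as with a
#' plain uniform integer generator). These surrogate sets are scattered
#' over the whole series and carry no relation to any transition; they
#' form the null distribution for the dispersion tests.
#'
#' @param n_points Points per set (the number of real change points);
#'   must be `>= 2` for dispersion to be defined.
#' @param N Series length.
#' @param cfg A [surrogate_config()].
#' @return An integer matrix, one set per row.
#' @export
draw_random_sets <- function(n_points, N, cfg = surrogate_config()) {
  n_points <- as.integer(n_points)
  N <- as.integer(N)
  if (n_points < 2L)
    stop("dispersion is undefined for fewer than 2 points", call. = FALSE)
  stopifnot(N >= 2L)
  with_seed(cfg$seed, {
    matrix(sample.int(N, n_points * cfg$n_sets, replace = TRUE),
           nrow = cfg$n_sets, byrow = TRUE)
  })
}

#' Dispersion statistics of a change-point set
#'
#' `iqr_pct` is the interquartile range of the points as a percentage of
#' the series length; `sigma_pct` is the standard deviation of a normal
#' distribution fitted to the points (which reduces to the sample SD,
#' denominator `n - 1`), again as a percentage of the series length.
#' Clustered change points give small values; points scattered uniformly
#' over the series give about 50% (IQR) and `100 / sqrt(12) ~ 28.9%`
#' (sigma).
#'
#' @param points Numeric vector of change-point indices (`>= 2` points).
#' @param N Series length.
#' @param quantile_type Quantile algorithm for the quartiles (default 7).
#' @return A percentage in `[0, 100]`.
#' @export
iqr_pct <- function(points, N, quantile_type = 7L) {
  stopifnot(length(points) >= 2L)
  q <- stats::quantile(points, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  (q[2] - q[1]) / N * 100
}

#' @rdname iqr_pct
#' @export
sigma_pct <- function(points, N) {
  stopifnot(length(points) >= 2L)
  stats::sd(points) / N * 100
}

#' Test whether change points cluster
#'
#' Compares the dispersion of the detected change points with that of
#' random surrogate sets drawn uniformly over the series. For each of the
#' `n_sets` surrogate sets (same size as the real set) both dispersion
#' statistics are computed; the real statistic is then compared with the
#' percentile confidence interval of the surrogate values. A real value
#' below the lower CI bound means the detected change points are
#' significantly more concentrated than chance — evidence for a genuine
#' transition.
#'
#' @param real_points Integer vector of detected change points (`>= 2`).
#' @param N Series length.
#' @param cfg A [surrogate_config()].
#' @return An object of class `dispersion_tests`: a list with one
#'   `dispersion_test` per statistic (`iqr`, `sigma`), each holding
#'   `statistic`, `real_value`, `surrogate_mean`, `ci` (lo, hi),
#'   `outside_ci`, and `below_ci`.
#' @export
run_dispersion_tests <- function(real_points, N, cfg = surrogate_config()) {
  sets <- draw_random_sets(length(real_points), N, cfg)
  iqr_s <- apply(sets, 1L, iqr_pct, N = N, quantile_type = cfg$quantile_type)
  sig_s <- apply(sets, 1L, sigma_pct, N = N)
  alpha <- (1 - cfg$ci_level) / 2
  one <- function(name, real, surr) {
    ci <- stats::quantile(surr, c(alpha, 1 - alpha),
                          type = cfg$quantile_type, names = FALSE)
    structure(list(statistic = name, real_value = real,
                   surrogate_mean = mean(surr), ci = ci,
                   outside_ci = real < ci[1] || real > ci[2],
                   below_ci = real < ci[1]),
              class = "dispersion_test")
  }
  structure(list(
    iqr = one("iqr_pct", iqr_pct(real_points, N, cfg$quantile_type), iqr_s),
    sigma = one("sigma_pct", sigma_pct(real_points, N), sig_s)
  ), class = "dispersion_tests")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("%s: real %.1f%%, surrogate mean %.1f%% (CI %.1f-%.1f%%) -> %s\n",
              x$statistic, x$real_value, x$surrogate_mean,
              x$ci[1], x$ci[2],
              if (x$below_ci) "clustered (below CI)"
              else if (x$outside_ci) "outside CI (above)"
              else "inside CI"))
  invisible(x)
}

#' @export
print.dispersion_tests <- function(x, ...) {
  print(x$iqr); print(x$sigma)
  invisible(x)
}
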