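#' Detection pipeline configuration
#'
#' Bundles every tunable of the convergent detection pipeline. The
#' defaults are the reference settings for daily self-rating data: weekly
#' (7-point) indicator windows, 20-point smoothing of the indicator
#' series (5 for instantaneous frequency, whose shape is smoother), a
#' 3-dimensional embedding with unit delay, a length-adaptive detection
#' penalty on z-scored rows, and 100 surrogate sets at 95% confidence.
#'
#' @param k Change-point penalty applied to every (z-scored) series
#'   entering the second-order layer. The default `NULL` uses a
#'   length-adaptive BIC-style penalty, `2 * log(N)` for a series of `N`
#'   points, so that spurious detections on stationary noise stay rare at
#'   every row length; a number fixes the penalty for all rows.
#' @param min_segment Minimum segment length for the detector.
#' @param dc_window,pe_window,spa_window Indicator window widths.
#' @param pe_order Permutation-entropy word length.
#' @param dc_range Optional fixed scale range for dynamic complexity;
#'   default observed min/max of the z-scored series.
#' @param smooth_window Moving average/variance window for DC, PE, and
#'   SPA.
#' @param if_smooth_window Moving average/variance window for IF.
#' @param embed_dim,embed_delay Recurrence-plot embedding parameters.
#' @param methods Which indicator families to run; any subset of
#'   `c("ts", "dc", "pe", "if", "spa", "rp")`.
#' @param rescale_rows If `TRUE` (default), every series entering the
#'   second-order change-point layer (indicator series, their smoothings,
#'   and the recurrence-plot rows) is z-scored first, so the penalty `k`
#'   acts on a comparable scale in every row; with `FALSE` the detector
#'   sees the indicators on their native scale, where weakly varying rows
#'   (e.g. a flat complexity profile) fall under the penalty and
#'   contribute nothing.
#' @param n_surrogates,ci_level,quantile_type Surrogate-test settings
#'   (see [surrogate_config()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = NULL, min_segment = 2L,
                            dc_window = 7L, pe_window = 7L, pe_order = 3L,
                            spa_window = 7L, dc_range = NULL,
                            smooth_window = 20L, if_smooth_window = 5L,
                            embed_dim = 3L, embed_delay = 1L,
                            methods = c("ts", "dc", "pe", "if", "spa", "rp"),
                            rescale_rows = TRUE,
                            n_surrogates = 100L, ci_level = 0.95,
                            quantile_type = 7L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.null(k) || k >= 0, dc_window >= 3L, pe_window > pe_order,
            spa_window >= 3L, smooth_window >= 2L, if_smooth_window >= 2L,
            embed_dim >= 1L, embed_delay >= 1L)
  structure(list(k = k, min_segment = as.integer(min_segment),
                 dc_window = as.integer(dc_window),
                 pe_window = as.integer(pe_window),
                 pe_order = as.integer(pe_order),
                 spa_window = as.integer(spa_window),
                 dc_range = dc_range,
                 smooth_window = as.integer(smooth_window),
                 if_smooth_window = as.integer(if_smooth_window),
                 embed_dim = as.integer(embed_dim),
                 embed_delay = as.integer(embed_delay),
                 methods = methods,
                 rescale_rows = isTRUE(rescale_rows),
                 n_surrogates = as.integer(n_surrogates),
                 ci_level = ci_level,
                 quantile_type = as.integer(quantile_type)),
            class = "pipeline_config")
}

# z-score a derived/raw series and run the two-statistic detector,
# mapping detected local indices to original time. Constant or too-short
# series contribute nothing.
detect_row <- function(d, cfg) {
  x <- series_values(d)
  times <- series_times(d)
  empty <- data.frame(time = integer(0), statistic = character(0))
  if (length(x) < 2L * cfg$min_segment) return(empty)
  sdev <- stats::sd(x)
  if (sdev == 0) return(empty)
  if (cfg$rescale_rows) x <- (x - mean(x)) / sdev
  kval <- if (is.null(cfg$k)) 2 * log(length(x)) else cfg$k
  cps <- detect_mean_and_variance(x, k = kval, min_segment = cfg$min_segment)
  if (nrow(cps) == 0L) return(empty)
  data.frame(time = times[cps$index], statistic = cps$statistic)
}

#' Run the convergent transition-detection pipeline
#'
#' The full second-order analysis of a series: the input is z-scored,
#' every first-order indicator is computed (dynamic complexity,
#' permutation entropy, instantaneous frequency via the Stockwell
#' transform, synchronization when a multivariate companion is supplied,
#' and the recurrence plot), and penalized change-point detection (one
#' mean and one variance change per series) is applied to the original
#' series, to each one-dimensional indicator, and to each indicator's
#' moving average and moving variance. The recurrence plot contributes
#' row-wise pooled change points. All detections are mapped back to
#' original time, pooled, and summarized by their mean and sample SD;
#' surrogate dispersion tests check whether the pool clusters more than
#' uniform random points would. The time-frequency matrix itself
#' contributes no row — it enters only through instantaneous frequency.
#'
#' @param s A `pt_series` (at least ~40 points so the window chains fit).
#' @param ms Optional `pt_multiseries` of the system's component
#'   variables or items, enabling the synchronization rows.
#' @param config A [pipeline_config()].
#' @param seed Optional integer seed for the surrogate draws.
#' @return An object of class `transition_report`; see
#'   [aggregate_changepoints()], [oversampling_variant()],
#'   [write_report()].
#' @export
run_pipeline <- function(s, ms = NULL, config = pipeline_config(),
                         seed = NULL) {
  if (!inherits(s, "pt_series")) s <- pt_series(s)
  n <- length(s$values)
  need <- max(config$dc_window + config$smooth_window,
              config$if_smooth_window, 4L * config$min_segment)
  if (n < need)
    stop(sprintf("series too short (%d points) for the smoothing chain (%d needed)",
                 n, need), call. = FALSE)
  if (stats::sd(s$values) == 0) {
    # a constant series carries no transition: every method row is empty
    empty <- data.frame(time = integer(0), statistic = character(0))
    labs <- c("TS", "DC", "MA of DC", "MV of DC", "PE", "MA of PE",
              "MV of PE", "IF", "MA of IF", "MV of IF", "RP")
    rows <- stats::setNames(rep(list(empty), length(labs)), labs)
    return(build_report(rows, n = n, config = config, seed = seed,
                        label = s$label, oversampling = FALSE))
  }
  z <- z_transform(s)
  rows <- list()
  if ("ts" %in% config$methods)
    rows[["TS"]] <- detect_row(z, config)
  if ("dc" %in% config$methods) {
    dc <- dynamic_complexity(z, window = config$dc_window,
                             range = config$dc_range)
    rows[["DC"]] <- detect_row(dc, config)
    rows[["MA of DC"]] <- detect_row(moving_average(dc, config$smooth_window),
                                     config)
    rows[["MV of DC"]] <- detect_row(moving_variance(dc, config$smooth_window),
                                     config)
  }
  if ("pe" %in% config$methods) {
    pe <- permutation_entropy(z, window = config$pe_window,
                              order = config$pe_order)
    rows[["PE"]] <- detect_row(pe, config)
    rows[["MA of PE"]] <- detect_row(moving_average(pe, config$smooth_window),
                                     config)
    rows[["MV of PE"]] <- detect_row(moving_variance(pe, config$smooth_window),
                                     config)
  }
  if ("if" %in% config$methods) {
    iff <- instantaneous_frequency(stockwell_transform(z))
    rows[["IF"]] <- detect_row(iff, config)
    rows[["MA of IF"]] <- detect_row(
      moving_average(iff, config$if_smooth_window), config)
    rows[["MV of IF"]] <- detect_row(
      moving_variance(iff, config$if_smooth_window), config)
  }
  if ("spa" %in% config$methods && !is.null(ms)) {
    zms <- pt_multiseries(lapply(ms$columns, function(v) {
      z_transform(pt_series(v))$values
    }), t0 = ms$t0)
    sp <- spa(zms, window = config$spa_window)
    rows[["SPA"]] <- detect_row(sp, config)
    rows[["MA of SPA"]] <- detect_row(moving_average(sp, config$smooth_window),
                                      config)
    rows[["MV of SPA"]] <- detect_row(moving_variance(sp, config$smooth_window),
                                      config)
  }
  if ("rp" %in% config$methods) {
    rm_ <- recurrence_matrix(z, dimension = config$embed_dim,
                             delay = config$embed_delay)
    rp <- rp_changepoints(rm_, k = config$k, min_segment = config$min_segment,
                          rescale = config$rescale_rows)
    rows[["RP"]] <- data.frame(time = rp$time, statistic = rp$statistic)
  }
  build_report(rows, n = n, config = config, seed = seed,
               label = s$label, oversampling = FALSE)
}

build_report <- function(rows, n, config, seed, label,
                         oversampling = FALSE) {
  pooled <- unlist(lapply(rows, function(r) r$time), use.names = FALSE)
  agg <- aggregate_changepoints(pooled)
  surrogate <- if (length(pooled) >= 2L) {
    run_dispersion_tests(pooled, n,
                         surrogate_config(n_sets = config$n_surrogates,
                                          seed = seed,
                                          ci_level = config$ci_level,
                                          quantile_type = config$quantile_type))
  } else NULL
  structure(list(label = label, rows = rows, pooled = pooled,
                 mean = agg$mean, sd = agg$sd,
                 n_points = agg$n, no_detection = agg$n == 0L,
                 series_length = n, surrogate = surrogate,
                 oversampling = oversampling,
                 config = config, seed = seed),
            class = "transition_report")
}

#' Pool change points into a location estimate
#'
#' @param points Integer vector of pooled change-point times.
#' @return A list with `mean` and `sd` (arithmetic mean and sample SD,
#'   rounded to integer time indices), `n`, and `single_point` (`TRUE`
#'   when only one point was found, in which case `sd` is reported as 0).
#'   An empty pool gives `n = 0` and `NA` location.
#' @export
aggregate_changepoints <- function(points) {
  n <- length(points)
  if (n == 0L)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                single_point = FALSE))
  list(mean = round(mean(points)),
       sd = if (n < 2L) 0 else round(stats::sd(points)),
       n = n, single_point = n == 1L)
}

#' Oversampling check: drop the smoothed rows
#'
#' The moving average and moving variance of an indicator resample the
#' same underlying information, so their change points could in principle
#' inflate the apparent convergence of the pool. This variant rebuilds
#' the report without every "MA of ..." and "MV of ..." row and re-runs
#' the surrogate tests on the reduced pool (same seed). If the reduced
#' pool still rejects randomness, the clustering is not an oversampling
#' artifact.
#'
#' @param report A `transition_report` from [run_pipeline()].
#' @return A new `transition_report` with `oversampling = TRUE`.
#' @export
oversampling_variant <- function(report) {
  stopifnot(inherits(report, "transition_report"))
  keep <- !grepl("^M[AV] of ", names(report$rows))
  build_report(report$rows[keep], n = report$series_length,
               config = report$config, seed = report$seed,
               label = report$label, oversampling = TRUE)
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report '%s'>%s series length %d\n", x$label,
              if (x$oversampling) " (oversampling variant)" else "",
              x$series_length))
  for (nm in names(x$rows)) {
    r <- x$rows[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                if (nrow(r) == 0L) "-"
                else paste(sprintf("%d (%s)", r$time, substr(r$statistic, 1, 1)),
                           collapse = ", ")))
  }
  if (x$no_detection) {
    cat("  no transition detected\n")
  } else {
    cat(sprintf("  pooled: n = %d, mean = %d (SD %d)\n",
                x$n_points, as.integer(x$mean), as.integer(x$sd)))
    if (!is.null(x$surrogate)) print(x$surrogate)
  }
  invisible(x)
}

report_table <- function(report) {
  do.call(rbind, c(lapply(names(report$rows), function(nm) {
    r <- report$rows[[nm]]
    if (nrow(r) == 0L)
      data.frame(method = character(0), time = integer(0),
                 statistic = character(0))
    else
      data.frame(method = nm, time = r$time, statistic = r$statistic)
  }), make.row.names = FALSE))
}

#' Write / read a transition report
#'
#' JSON keeps the full report (per-method change points, pooled summary,
#' surrogate tests); CSV keeps the per-method change-point table. Reading
#' either back reconstructs the change-point content; the pooled list
#' round-trips exactly.
#'
#' @param report A `transition_report`.
#' @param path Output file.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return The path, invisibly (`write_report`); a list with `rows` (the
#'   change-point table) and `pooled` (`read_report`).
#' @export
write_report <- function(report, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  tab <- report_table(report)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  surr <- if (!is.null(report$surrogate)) {
    lapply(report$surrogate, function(d) {
      list(statistic = d$statistic, real_value = d$real_value,
           surrogate_mean = d$surrogate_mean,
           ci = as.numeric(d$ci), outside_ci = d$outside_ci,
           below_ci = d$below_ci)
    })
  }
  out <- list(schema = "ptdetect/report/1",
              label = report$label,
              series_length = report$series_length,
              oversampling = report$oversampling,
              changepoints = tab,
              pooled = report$pooled,
              mean = report$mean, sd = report$sd,
              n_points = report$n_points,
              no_detection = report$no_detection,
              surrogate = surr,
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(list(rows = tab, pooled = as.integer(tab$time)))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(rows = obj$changepoints, pooled = as.integer(obj$pooled),
       mean = obj$mean, sd = obj$sd, surrogate = obj$surrogate,
       series_length = obj$series_length)
}
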