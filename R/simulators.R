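#' Henon map with a ramped control parameter
#'
#' Iterates the two-dimensional Henon map
#' `x[k+1] = y[k] + 1 - a * x[k]^2`, `y[k+1] = b * x[k]` with the control
#' parameter `a` held at `a_start` for the first `pre` iterations, ramped
#' linearly (step `step` per iteration) across the transition window, and
#' held at `a_end` for the remaining `post` iterations. At the default
#' parameters the dynamics move from deterministic chaos to a regular
#' rhythm across the ramp — a phase transition with a known window,
#' useful as ground truth for the detection pipeline. The map is purely
#' deterministic, so the orbit is bit-reproducible.
#'
#' @param a_start,a_end Control parameter before/after the ramp (defaults
#'   1.20 and 1.25).
#' @param step Per-iteration increment of `a` during the ramp (default
#'   0.002).
#' @param b Second map parameter (default 0.30).
#' @param x0,y0 Initial state (default 0, 0; not part of the output).
#' @param pre Iterations before the ramp (default 124).
#' @param ramp Integer window `c(first, last)` of ramp iterations
#'   (default `c(125, 150)`; `a` reaches `a_end` at the last).
#' @param post Iterations after the ramp (default 150).
#' @return A list with `series` (a `pt_series` of the `x` variable),
#'   `xy` (a `pt_multiseries` of both map variables, for synchronization
#'   analysis), and `truth` (the ramp window).
#' @export
simulate_henon <- function(a_start = 1.20, a_end = 1.25, step = 0.002,
                           b = 0.30, x0 = 0, y0 = 0,
                           pre = 124L, ramp = c(125L, 150L), post = 150L) {
  n <- pre + (ramp[2] - ramp[1] + 1L) + post
  xs <- numeric(n)
  ys <- numeric(n)
  x <- x0; y <- y0
  for (k in seq_len(n)) {
    a <- if (k < ramp[1]) a_start
         else if (k <= ramp[2]) min(a_start + step * (k - ramp[1]), a_end)
         else a_end
    xn <- y + 1 - a * x^2
    yn <- b * x
    if (!is.finite(xn) || abs(xn) > 1e6)
      stop("Henon orbit diverged at iteration ", k, call. = FALSE)
    x <- xn; y <- yn
    xs[k] <- x; ys[k] <- y
  }
  list(series = pt_series(xs, label = "henon_x"),
       xy = pt_multiseries(list(x = xs, y = ys)),
       truth = as.integer(ramp))
}

#' Generic regime-shift simulator
#'
#' Generates a short stochastic series containing a transition window
#' across which designated parameters ramp linearly — a ground-truth
#' test bed emulating the kinds of change seen in daily self-rating data.
#' The signal is `level + amplitude * sin(2 * pi * phase) + AR(1) noise`;
#' the available shift kinds compose:
#' \describe{
#'   \item{mean}{the level rises by `mean_shift` noise SDs,}
#'   \item{variance}{the noise SD is multiplied by `var_factor`,}
#'   \item{frequency}{the oscillation frequency moves from
#'     `freq_range[1]` to `freq_range[2]` cycles/sample (phase-continuous,
#'     leaving mean and variance unchanged),}
#'   \item{pattern}{the AR(1) coefficient moves from `ar_range[1]` to
#'     `ar_range[2]` with the innovation SD adjusted to keep the marginal
#'     noise variance constant.}
#' }
#' With `n_components > 1` a coupled system is generated: each component
#' shares a common latent signal whose loading ramps from
#' `sync_range[1]` to `sync_range[2]`, so inter-component correlation
#' rises across the window (for testing the synchronization indicator).
#'
#' @param length Series length (default 300).
#' @param window Transition window `c(t1, t2)` (default `c(150, 160)`).
#' @param kinds Character subset of
#'   `c("mean", "variance", "frequency", "pattern")` (default "mean");
#'   ignored in favor of a pure-noise null when `null = TRUE`.
#' @param mean_shift Level shift in units of the noise SD (default 3).
#' @param var_factor Post-window noise SD multiplier (default 4).
#' @param freq_range Start/end oscillation frequency in cycles/sample
#'   (default `c(0.05, 0.2)`).
#' @param amplitude Oscillation amplitude, used when "frequency" is among
#'   `kinds` (default 1).
#' @param ar_range Start/end AR(1) coefficient (default `c(0.6, -0.6)`).
#' @param noise_sd Baseline noise SD (default 1).
#' @param n_components Number of coupled components (default 1).
#' @param sync_range Start/end loading of the shared latent signal for the
#'   multivariate variant (default `c(0.2, 0.9)`).
#' @param null If `TRUE`, generate an i.i.d. noise control with no shift.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A list with `series` (a `pt_series`; the first component when
#'   `n_components > 1`), `multiseries` (a `pt_multiseries` or `NULL`),
#'   and `truth` (the transition window, or `NULL` for a null run).
#' @export
simulate_regime_shift <- function(length = 300L, window = c(150L, 160L),
                                  kinds = "mean", mean_shift = 3,
                                  var_factor = 4,
                                  freq_range = c(0.05, 0.2),
                                  amplitude = 1,
                                  ar_range = c(0.6, -0.6),
                                  noise_sd = 1, n_components = 1L,
                                  sync_range = c(0.2, 0.9),
                                  null = FALSE, seed = NULL) {
  n <- as.integer(length)
  window <- as.integer(window)
  if (!null && !(window[1] >= 1L && window[1] < window[2] && window[2] <= n))
    stop("invalid transition window", call. = FALSE)
  bad <- setdiff(kinds, c("mean", "variance", "frequency", "pattern"))
  if (length(bad) > 0L)
    stop("unknown shift kind: ", paste(bad, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    # ramp(t): 0 before the window, 1 after, linear inside
    ramp <- pmin(pmax((seq_len(n) - window[1]) /
                        max(window[2] - window[1], 1L), 0), 1)
    if (null) ramp <- numeric(n)
    level <- if ("mean" %in% kinds && !null)
      ramp * mean_shift * noise_sd else numeric(n)
    sdv <- if ("variance" %in% kinds && !null)
      noise_sd * (1 + ramp * (var_factor - 1)) else rep(noise_sd, n)
    osc <- numeric(n)
    if ("frequency" %in% kinds && !null) {
      phase <- cumsum(freq_range[1] + ramp * diff(freq_range))
      osc <- amplitude * sin(2 * pi * phase)
    }
    phi <- if ("pattern" %in% kinds && !null)
      ar_range[1] + ramp * diff(ar_range) else rep(0, n)
    # AR(1) noise with time-varying coefficient; innovation SD scaled so
    # the marginal variance stays sdv[t]^2 regardless of phi
    gen_noise <- function() {
      innov <- stats::rnorm(n)
      e <- numeric(n)
      prev <- 0
      for (t in seq_len(n)) {
        e[t] <- phi[t] * prev + sdv[t] * sqrt(1 - phi[t]^2) * innov[t]
        prev <- e[t]
      }
      e
    }
    if (n_components > 1L) {
      latent <- stats::rnorm(n, sd = noise_sd)
      lam <- sync_range[1] + ramp * diff(sync_range)
      comps <- lapply(seq_len(n_components), function(i) {
        level + osc + sqrt(1 - lam^2) * gen_noise() + lam * latent
      })
      names(comps) <- paste0("V", seq_len(n_components))
      ms <- pt_multiseries(comps)
      list(series = pt_series(comps[[1]], label = "V1"),
           multiseries = ms,
           truth = if (null) NULL else window)
    } else {
      list(series = pt_series(level + osc + gen_noise(), label = "x"),
           multiseries = NULL,
           truth = if (null) NULL else window)
    }
  })
}
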