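---
title: "Convergent detection of phase transitions in short time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent detection of phase transitions in short time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptdetect)
```

## The problem

Psychotherapeutic change processes, and self-organizing systems more
generally, often reorganize in sudden jumps: a control parameter drifts,
the old dynamic pattern destabilizes, and the system settles into a new
regime. In daily self-rating data these *phase transitions* (or, when not
all strict criteria are verifiable, *order transitions*) rarely announce
themselves as a clean step in the mean. They can appear as a change of
variance, of rhythm, of recurrence structure, of entropy, or of the
synchronization among a system's components — on series that are short
(80–300 points), noisy, coarse-grained, and non-stationary.

No single indicator is trustworthy under these conditions. `ptdetect`
therefore runs several indicators in parallel and asks whether their
change points *converge*: a second-order change-point layer is applied to
the original series, to every one-dimensional indicator series, and to
smoothed versions of those indicators; all detected change points are
pooled, and the pool's concentration is tested against change-point sets
placed uniformly at random on the series. A genuine transition produces a
cluster; indicator noise does not.

## The change-point detector

The elementary detector splits a series $x$ of length $N$ into two
segments $x_1, x_2$ and accepts the split when

$$C(x_1) + C(x_2) + k < C(x),$$

where the cost of a segment is $C(x) = N \cdot \mathrm{var}(x)$ (sample
variance, denominator $N-1$; segments shorter than 2 cost 0) for
mean-shift detection, and $C(x) = N \cdot \log(\max(\mathrm{var}(x),
10^{-12}))$ — the Gaussian log-likelihood cost — for variance-shift
detection. Every admissible split is evaluated (no approximation is
needed at these lengths; the scan is vectorized over cumulative sums),
the best split must beat the penalty $k$, ties go to the earliest index,
and the reported index is the first point of the *new* segment. Each
series may contribute at most two change points: one mean change, one
variance change.

Worked example: for $\{2,2,2,4,4,4,4,4,4,4\}$ the full-series cost is
$10 \cdot 0.933 = 9.33$; splitting before the fourth point gives two
constant segments with total cost $0$, so the mean change is reported at
index 4.

### The penalty

On a z-scored stationary noise series of length 300, the best single
split of the mean cost drops the total by several units purely by
chance (the maximum of a scan statistic), and the variance cost by more.
A fixed penalty of $k = 1$ therefore flags a change on essentially
*every* series of that length — it is a usable setting only for very
short series (it is, for instance, the natural choice for the 10-point
worked example above, and `cpa_config()` keeps `k = 1` as its default
for direct, single-series use). For the pipeline, whose rows range from
~280 to 300 points and which must stay quiet on stationary rows, the
default penalty is length-adaptive, $k = 2\log N$ — the BIC penalty for
the two parameters a single change point adds. Measured on z-scored
i.i.d. noise of length 300 this keeps the per-row false-alarm rate near
15% (the variance statistic has the heavier tail), while genuine shifts
in the simulators produce cost drops one to two orders of magnitude
above it. A numeric `k` in `pipeline_config()` overrides the adaptive
rule.

Every series entering the second-order layer is z-scored first
(`rescale_rows = TRUE`), so the penalty acts on a comparable scale
regardless of whether the row is a raw self-rating, a complexity profile
in $[0,1]$, or a recurrence-plot row of distances. The variance-shift
decision is scale-invariant either way; rescaling matters only for the
mean statistic.

### Degenerate inputs

The variance cost clamps zero variance at $\varepsilon = 10^{-12}$.
With the minimum segment length of 2, an *exactly constant* run at the
edge of a series can therefore attract a variance change point with a
large nominal cost drop: the constant prefix's clamped cost is hugely
negative. Coarse, strongly quantized indicator series (permutation
entropy takes finitely many values; low-noise simulations can produce
near-constant stretches) occasionally trigger this. We keep the behavior
— it is what the cost function says — but flag it here: on heavily tied
data, inspect variance change points that sit very close to a series
edge. Constant series and constant recurrence-plot rows are skipped
outright and contribute nothing.

## The indicators

**Dynamic complexity (DC)** is the product of a fluctuation measure $F$
and a distribution measure $D$ in a trailing window of 7 points (one
week of daily ratings). The underlying construction is published in
toolbox form rather than as printed formulas, so this package fixes
concrete operationalizations and documents them prominently:

* $F$: the window is split into maximal strictly monotone runs
  (plateaus break runs; they contribute nothing either way); each run
  contributes $|\Delta \text{value}| / \Delta t$, and the sum is divided
  by $(x_{max}-x_{min}) \cdot (m-1)$, the steepest signal the scale
  permits. $F = 0$ for a constant window, $F = 1$ for full-range
  alternation at every step, and a monotone full-range ramp over a
  7-point window scores $1/36$.
* $D$: sorted window values are compared with an ideal uniform grid from
  $x_{min}$ to $x_{max}$;
  $D = \max(0,\, 1 - \sum_i |y_{(i)} - g_i| / (m (x_{max}-x_{min})/2))$,
  so an even spread over the full range scores 1 and total collapse onto
  one end of the scale scores 0 (a window collapsed on mid-scale scores
  $3/7$ at $m = 7$).

Both use a scale range: nominal rating-scale bounds when known,
otherwise the observed global min/max (`dc_range`). Out-of-range values
(possible after noise is added to simulations) are clipped rather than
rejected. DC rises before transitions — critical fluctuations — which
makes it an early-warning signal as well as a locator.

**Permutation entropy (PE)** maps every word of 3 consecutive values
inside a 7-point trailing window to its ordinal pattern (ranks, with
ties broken by order of occurrence — essential for coarse rating scales,
where exact ties are common) and reports the Shannon entropy of the
pattern frequencies normalized by $\log 3!$ to $[0,1]$. Rank-based, it
is invariant under any strictly monotone transformation of the data.

**Stockwell transform and instantaneous frequency (IF).** The S-transform
combines the absolutely referenced phase of the short-time Fourier
transform with frequency-adaptive Gaussian windows. We use the discrete
frequency-domain formulation: for voice $n$, the signal's DFT is shifted
by $n$, multiplied by $\exp(-2\pi^2 m^2/n^2)$ (circularly wrapped
frequency offsets $m$), and inverse-transformed over time; the series
mean is removed first and the zero-frequency voice is excluded
downstream. IF reduces the time–frequency matrix to one series — the
first conditional spectral moment, i.e. the power-weighted
($\text{amplitude}^2$) mean frequency per time point. Two consequences
of this construction are worth knowing:

* the transform is circular, so a large level difference between the
  series' ends can leak into the outermost columns; and
* the analysis bandwidth grows with frequency, so the IF of white noise
  sits near 0.32 cycles/sample, above the naive flat-spectrum midpoint
  of 0.25 (the package's Monte-Carlo tests pin this value down).

Neither matters for the pipeline, which only asks *where IF changes*.
IF is produced at full series length; reference implementations in
commercial environments return fewer points (edge trimming), which is a
known, documented difference — downstream change points, not pointwise
values, are the contract.

**Synchronization pattern analysis (SPA)** applies when a multivariate
companion is supplied (questionnaire items, or a model system's other
variables): within each trailing 7-point window, the absolute Pearson
correlations of all column pairs are averaged. Pairs in which a column
is constant within the window are excluded rather than scored 0 — flat
windows are common in rating data and a forced 0 would bias coherence
downward; windows with no valid pair are dropped with the time
bookkeeping preserved. For univariate input the SPA rows are simply
absent from the report.

**Recurrence plots (RP).** The series is embedded with 3 time-delay
coordinates at delay 1, and all pairwise Euclidean distances between the
embedded vectors form the (unthresholded) recurrence matrix —
thresholding it into a binary plot would add an undocumented radius
parameter, and the distances carry strictly more information. The
change-point detector is applied to *every row* of the matrix; detected
indices are pooled per statistic and their arithmetic mean (rounded to
the nearest integer, mapped through the embedding offset) is the plot's
change point. Rows with no detection are skipped, not counted as zeros;
a statistic with no detections anywhere contributes nothing.

## The second-order layer

`run_pipeline()` z-scores the input, computes DC, PE, IF, SPA (if
multivariate input is given) and the RP, and runs the detector on:

| row | source | smoothing |
|---|---|---|
| TS | original (z-scored) series | — |
| DC, MA of DC, MV of DC | dynamic complexity | 20-point moving average / variance |
| PE, MA of PE, MV of PE | permutation entropy | 20-point |
| IF, MA of IF, MV of IF | instantaneous frequency | 5-point |
| SPA, MA of SPA, MV of SPA | synchronization | 20-point |
| RP | row-wise pooled recurrence change points | — |

All windowed quantities use *trailing* windows — the value computed from
points $t-w+1, \dots, t$ is stamped at time $t$. Centered windows would
shift estimates half a window earlier, but trailing alignment is the
only choice available to prospective, real-time monitoring, which is the
intended use. Every derived index is mapped back to original time
through the chain of window offsets, so rows of different native lengths
report in one coordinate system.

Detections from all rows are pooled; the pool's arithmetic mean and
sample SD summarize the transition estimate (both rounded to integer
time indices in the report; a single-point pool is flagged and reported
with SD 0). The time–frequency matrix itself contributes no row: it has
no one-dimensional quantification of its own and enters only through IF.

## Surrogate validation

Whether the pooled change points actually cluster is tested against
chance: `n_sets = 100` surrogate sets of the same size are drawn
uniformly (with replacement) on $\{1..N\}$, and two dispersion
statistics are computed for the real pool and every surrogate set —

* **IQR%**: interquartile range as a percentage of the series length
  (linear-interpolation quartiles, `quantile type 7`; the convention is
  exposed because reference environments differ). Uniform sets of ~23
  points average about 46–47%.
* **σ%**: the standard deviation of a fitted normal distribution — which
  for a maximum-likelihood fit is just the sample SD (we use the
  $n-1$ denominator; the difference is negligible at these sizes) —
  again as % of length. Uniform draws converge to
  $100/\sqrt{12} \approx 28.87\%$.

The 95% interval over the surrogate values is a percentile interval —
the only construction that needs no distributional assumption. A real
statistic *below* the lower bound means the change points are
significantly more concentrated than chance. Calibration is part of the
test suite: with uniform "real" points the rejection rate over 500
replicates stays in the 1–12% band around the nominal 5%.

`oversampling_variant()` repeats the pooling and the tests without the
"MA of …" and "MV of …" rows, which resample information already present
in their parent indicator and could inflate apparent convergence.

## Simulators and what the tests do (and do not) show

`simulate_henon()` iterates $x_{k+1} = y_k + 1 - a x_k^2$,
$y_{k+1} = b x_k$ from the origin with $b = 0.30$: 124 points at
$a = 1.20$ (deterministic chaos), a linear ramp of $a$ by 0.002 per step
across iterations 125–150 ending at $a = 1.25$, and 150 further points
there (the orbit locks into a period-7 rhythm) — 300 points with a known
transition window. We anchor the ramp so that $a$ *reaches* its end
value at iteration 150; the counting convention treats the 124 pre-ramp
iterations as generated points, so the series has length 300 exactly.
The map is deterministic and bit-reproducible. A noteworthy feature of
this particular orbit: the chaotic segment shadows the later rhythm
around iterations ~75–105, and several indicators (PE, DC, the RP rows)
genuinely respond there — the pooled pipeline still centers on the true
window, but the pool is wider than the transition alone would suggest.

`simulate_regime_shift()` is a generic ground-truth generator standing
in for process models whose equations are not public: a stochastic
signal whose designated parameters ramp linearly across a transition
window (defaults: length 300, window 150–160, baseline noise SD 1).
Shift kinds compose — a level shift of 3 noise-SDs, a 4-fold noise-SD
increase, a phase-continuous oscillation frequency shift from 0.05 to
0.2 cycles/sample, and an AR(1)-coefficient ("pattern") shift with the
marginal variance held fixed. A multivariate variant shares a latent
signal whose loading ramps, so component synchronization rises across
the window. Real phase transitions change several dynamic features at
once, so the end-to-end recovery tests use composite shifts
(mean + variance + pattern) as the representative scenario; the median
location error over 20 seeds is at most 10 samples there. Pure
single-feature shifts are harder: the rows blind to that feature
contribute only scan noise, and the pooled mean scatters accordingly
(the pure mean step's median error is roughly twice as large). The
frequency-shift case demonstrates the method's reason for existing: the
detector finds nothing on the raw series and the transition is carried
entirely by the IF rows.

The generators emulate shift structure and dynamic noise. They do not
emulate integer-valued rating scales, item-level measurement structure,
missing days, retrospective rating biases, or weekly periodicity in
empirical monitoring data — passing tests show that the machinery
recovers known transitions in clean stochastic analogues, not that every
empirical series with these properties will yield an unambiguous
cluster.

## Numerical and design choices, in one place

* Sample variance (denominator $n-1$) everywhere; forced by the
  cost-function walkthrough above.
* Time indices are 1-based; a change point is the first index of the new
  segment; ties break to the smallest index.
* `min_segment = 2`: variance is undefined on singletons.
* Variance detection centers each segment by its own mean (implicit in
  the per-segment variance).
* Trailing windows throughout; derived position $i$ maps to original
  time $\text{offset} + i - 1$.
* The DC scale range defaults to the observed global min/max of the
  (z-scored) series; within-window ranges would make windows
  incomparable.
* PE uses natural logarithms with $\log n!$ normalization.
* Surrogate draws allow duplicates (plain uniform integer generator);
  quartiles and percentile CIs use `quantile type 7` unless configured
  otherwise.
* The row-wise RP pooling skips non-detecting rows; the pooled RP index
  is rounded to the nearest integer because reports carry integer time
  indices.
* Problem sizes in the shipped tests: series length 300, 100 surrogate
  sets, 500 calibration replicates, 20 recovery seeds.

## Known limitations

* One change point per statistic per row: staircase processes with
  several genuine transitions will report only the dominant one per row.
* The pooled mean is a flat average over rows; rows that are
  uninformative for a given shift type contribute scan noise. The
  surrogate tests guard against over-reading such pools, at the price of
  conservatism: a pool split between a genuine precursor episode and the
  main transition (as in the Hénon orbit above) can fail the IQR
  clustering test while the σ test still rejects — the package reports
  both rather than merging them into one verdict.
* The S-transform's circularity and frequency-dependent bandwidth make
  pointwise IF values near the series edges, and under broadband noise,
  interpretable only relative to themselves over time.
* No missing-data handling, irregular sampling, or streaming operation;
  ingestion expects complete, regularly sampled series.
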