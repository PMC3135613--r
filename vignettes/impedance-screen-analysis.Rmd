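---
title: "Analyzing time-resolved impedance proliferation screens"
author: "cigrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing time-resolved impedance proliferation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigrscreen)
```

## The measurement and its two problems

Impedance-based real-time cell analyzers record, for every well of a
96-well plate, a unit-less *cell index* (CI) that grows with the number
and adhesion quality of the cells attached to the electrodes at the well
bottom. In an RNAi proliferation screen each well carries one siRNA
knockdown, and the instrument yields a CI curve per well over tens of
hours — a time-resolved phenotype instead of the usual single end point.

Raw CI has two properties that get in the way of screening statistics.
First, absolute CI depends on how many cells happened to be seeded, so
traces are normalized to the reading at a reference time $t_0$:

$$\mathrm{NCI}_s(t) = \frac{\mathrm{CI}_s(t)}{\mathrm{CI}_s(t_0)},$$

which is 1 at $t_0$ by construction but leaves the choice of $t_0$
arbitrary. Second, CI accumulates: a reading at time $t$ carries every
measurement fluctuation since the start, so the variance of CI across
biological replicates grows over time.

Both problems disappear under the first-order derivative. The
*cell-index growth rate* (CIGR) on a uniform grid with step
$\Delta t$ is the forward difference

$$\mathrm{CIGR}_s(t_i) =
  \frac{\mathrm{CI}_s(t_{i+1}) - \mathrm{CI}_s(t_i)}{\Delta t},$$

assigned to the left grid point, in cell-index units per hour. Its sign
reads directly as growing / in recession / constant, its noise is
stationary in time, and summing it back recovers the CI trace exactly
(`cigr_transform()` is a left inverse of discrete integration — the
package tests this identity to $10^{-9}$). `average_cigr()` over a time
domain telescopes to the end-point slope
$(\mathrm{CI}(t_N)-\mathrm{CI}(t_1))/(t_N-t_1)$, which is what makes it
comparable to an end-point viability readout.

Division by $\Delta t$ makes the quantity grid-independent; the
undivided successive differences (a plain `diff()` of the trace) are
available behind `raw_diff = TRUE` for compatibility with conventions
that report raw differences.

## Grid, interpolation and defaults

Instruments record on mixed cadences (e.g. every 15 minutes early,
hourly later), so each well is first interpolated onto a uniform
half-hour grid. The default analysis domain is 13–58 h post
transfection at 0.5 h steps — 91 grid points — with normalization at
$t_0 = 8$ h; all defaults are arguments (`uniform_grid()`, `t0_h`).

Interpolation uses the classic FMM cubic interpolating spline
(`stats::spline`). An interpolating (not smoothing) spline preserves the
recorded values at the knots; the FMM end condition reproduces cubic
polynomials exactly, which a natural spline (zero second derivative at
the boundary) cannot. No extrapolation is performed: a grid extending
beyond a well's recorded range is an error naming the well. Wells with
more than 20% missing readings (configurable) are excluded from plate
statistics and listed in the analysis object; interior missing readings
below the threshold are simply omitted from that well's spline fit.

## Assay quality in the time domain

The screening-window coefficient for a positive/negative control pair is

$$Z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|},$$

bounded above by 1, with $Z \ge 0$ conventionally read as an assay good
enough to screen. `time_dependent_zfactor()` evaluates this per time
point on the replicate means and $n-1$ standard deviations of control
CIGR curves, giving a quality *curve* rather than a number: one sees
not just whether controls separate but *when*. Time points with equal
means yield `NA` rather than aborting, so 91-point curves stay
reportable; `zfactor_window()` reports the longest contiguous stretch
with $Z$ above a floor.

## Normalization and replicate combination

Systematic plate effects (an incubator gas-supply change mid-screen is
the canonical example) shift whole plates. Per plate, the average CIGR
of every well is therefore z-scored against the plate's *sample* wells:
controls are scored against that reference but excluded from it, since
including known strong inhibitors would inflate the reference spread.
The same standardization applied per time point
(`timeseries_zscore()`) yields each gene's z-curve. Reference wells
have mean 0 and sd 1 per plate and per time point by construction
(tested to $10^{-9}$), and an injected two-batch shift collapses to
below 0.05 sd after normalization.

Each siRNA is screened on two biological replicate plates. For
combining the two z-scores the package offers three rules:

* `"stouffer"` (default): $\sum_i z_i / \sqrt{n}$. Preserves sign and is
  itself standard normal when the replicates are null, so a fixed
  cut-off such as 1.96 keeps its nominal false-positive rate after
  combination.
* `"rms"`: the signed root-mean-square
  $\mathrm{sign}(\bar z)\sqrt{\tfrac1n\sum z_i^2}$, a summary used in
  screening practice; its magnitude is what a pure RMS reports, with
  the sign re-attached so inhibitors and activators stay
  distinguishable (`rms_summarize(..., signed = FALSE)` gives the pure
  RMS). Under a two-replicate null, $P(|\mathrm{RMS}| \ge 1.96) =
  e^{-1.96^2} \approx 2.15\%$, i.e. a fixed 1.96 cut is conservative
  rather than nominal — the reason it is not the default.
* `"mean"`: the plain replicate mean, for completeness.

This is a genuinely open design point: rank-based "top 5%" selection is
self-calibrating under any summary, but a fixed-threshold rule is only
calibrated if the combined statistic is standard normal under the null,
which singles out the Stouffer combination.

## Hit calling

**Constant modulators.** `constant_hits()` selects genes with
$|z| \ge$ `z_threshold(alpha)` (two-sided normal quantile; 1.96 at
$\alpha = 0.05$), inclusive at the boundary, ranked by $|z|$; negative
z-scores are inhibitors of proliferation, positive activators.

**Transient modulators.** Many knockdowns act only in a time window.
The detector is a flooded-relief construction: raise the "water level"
to the cut-off and keep the maximal runs of consecutive grid points
where the z-curve stays beyond it ($z \ge +c$ or $z \le -c$). A run of
$k$ points counts as $k \Delta t$ hours (three half-hour points = 1.5
h), and only runs lasting at least the minimum window (default 3 h)
qualify — this removes one-point spikes that are significant at a
single measurement. The peak is the maximum $|z|$ over qualifying runs,
earliest time on ties; when both directions qualify, the direction of
the global maximum wins but both directions' intervals are retained.
The construction reduces exactly to thresholded run-length detection,
so no image-processing watershed machinery is involved; the
implementation is checked against a brute-force enumerate-all-intervals
oracle on a thousand random 91-point curves.

Peak times are binned into kinetic classes: early (< 30 h),
intermediate (30–45 h), late (≥ 45 h). The boundaries themselves are
assigned upward (30 h is intermediate, 45 h late) — the bin edges'
membership is a recorded package choice, as verbal definitions of such
bins usually leave the edges open. `sweep_hits()` counts hits over
$\alpha \in \{0.01, 0.05, 0.10\}$ crossed with eight windows spanning
1.5–6 h; counts can only fall as either parameter tightens, and the
implementation verifies that monotonicity on every run. The published
sweep range 1.5–6 h does not uniquely determine the eight window
values; the default takes half-hour steps to 4 h and then 5 h and 6 h,
i.e. `c(1.5, 2, 2.5, 3, 3.5, 4, 5, 6)`, all multiples of the grid step.

## The synthetic-screen generator

Real screens cannot ship with a package; a seeded generator encodes the
phenomenology the analysis must handle, and every claim the package
makes about itself is demonstrated on it. Cells grow logistically with
a time-varying instantaneous rate

$$r(t) = g \cdot \ell(t) \cdot
  \bigl(1 + A e^{-t/\tau}\cos(2\pi t/P + \varphi)\bigr) \cdot e(t)
  \cdot b,$$

with $g$ the baseline rate, $\ell(t)$ a smooth post-transfection lag
ramp, a damped oscillation (cell-cycle synchronization by the
transfection, desynchronizing over time), $e(t)$ the knockdown's
multiplicative effect on growth, and $b$ a batch factor. Because the
logistic equation with time-varying rate has the closed form
$N(t) = K/(1 + (K/N_0 - 1)e^{-R(t)})$ with $R(t) = \int_0^t r$, wells
are simulated exactly (trapezoidal accumulation of $R$ on a 0.1 h
internal grid), not by stochastic stepping. Cell index is
`ci_per_cell` $\times\, N(t)$; measurement noise is added to each
successive *increment* of the trace — a random walk — so CI variance
grows over time while CIGR noise stays stationary, which is precisely
the variance structure the CIGR transform is designed for. A
white-noise-on-readings alternative (`noise = "white"`) exists for
contrast tests.

Defaults and the reasoning behind them:

* `lag_h = 30`, with a logistic ramp (`lag_scale_h = 4`) rather than a
  hard switch — observed growth curves are smooth. The ramp rises from
  `lag_base = 0.3` of the full rate, not from zero: wells do grow
  during the lag, just slower, and a zero floor would make any
  early-acting inhibitor undetectable in principle (there would be
  nothing to inhibit).
* `osc_period_h = 17`, amplitude 0.3, damping 30 h. The oscillation
  phase is common across the screen with small per-plate jitter
  (`phase_jitter_sd = 0.3` rad): transfection synchronizes all plates
  alike, so full per-plate phase randomization would cancel the
  population-mean oscillation that is plainly visible in real screens.
* `growth_rate_per_h = 0.05`, `n0 = 10000` seeded cells,
  `carrying_capacity = 5e6`. The capacity is deliberately far above the
  cell numbers reached in a screen window — saturation matters only in
  long seeding-density experiments, where the noiseless maximum CIGR is
  linear in the seeded cell number over the exponential phase
  ($R^2 > 0.99$ across 3000–30000 cells).
* `increment_noise_sd = 0.002` per measured increment, and small
  biological well-to-well variation (`n0_cv = 0.05`,
  `rate_cv = 0.005`). These magnitudes are *calibrated*, not measured:
  they are chosen so that control Z-factor curves stay at or above zero
  over a > 20 h window and replicate CIGR variance is time-stable while
  CI variance accumulates — the qualitative behavior of the real
  instrument — and they should be read as that calibration, not as
  ground truth about any particular machine. A consequence worth
  knowing: the time-stable CIGR variance regime requires replicate
  variability to be dominated by measurement noise, which is why the
  per-well growth-rate CV is small.
* The batch effect (`plate_shift = 0.15` from rack 7 of 11 onward) is a
  multiplicative growth-rate factor, not an additive CI offset: an
  additive constant would vanish under differencing and could never
  reproduce the observed jump in average CIGR between batches. A
  changed incubator gas supply plausibly changes growth itself.
* Geometry: 80 sample wells per rack plus column 12 holding duplicate
  controls (non-targeting negative; three strong inhibitor positives
  with distinct kinetics, one of them late-onset), two replicate plates
  per rack. An 859-gene library therefore occupies 11 racks and 22
  plates.

Per-well seeds are derived from the master seed and the well's plate
position, so output is byte-identical under a fixed seed and a well's
trace does not depend on how much library surrounds it.

What the generator does *not* emulate: biophysical impedance detail
(electrode geometry, adhesion-quality changes without cell-number
changes), apoptosis/detachment dynamics beyond growth-rate modulation,
spatial within-plate gradients, and heavy-tailed or correlated
measurement noise. Passing tests on synthetic screens therefore
demonstrate the correctness and calibration of the *statistics*, not
the biology of any particular cell system.

## Numerical choices and degenerate inputs

* Standard deviations use the $n-1$ denominator throughout.
* Thresholds are inclusive ($|z| \ge c$); peak ties break to the
  earliest time.
* Zero reference variance: an error for scalar plate z-scores, a
  missing column for per-time-point z-scores (one bad time point should
  not kill a 91-point curve).
* `normalize_ci()` refuses wells with zero or missing reference
  reading, naming them; readers reject negative times, duplicate
  (well, time) pairs and non-monotone time headers.
* Tiny negative spline overshoot (within $10^{-9}$) is clamped to zero
  so non-negativity of CI survives interpolation.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
generated data: a full-size null screen (859 genes, 11 racks × 2
plates) for type-I calibration, a 264-gene two-batch screen for
batch-effect removal, twenty 88-gene screens with configured early
inhibitors and late activators for kinetic-ordering recovery, and a
thousand random z-curves for the detector-versus-oracle comparison.
These sizes were chosen so the whole validation runs in well under a
minute on a laptop while still exercising the library-scale geometry.

## Worked example

```{r example, eval = FALSE}
library(cigrscreen)

lib <- example_library(n = 88, n_inhibitors = 8, n_activators = 8)
scr <- simulate_screen(sim_config(seed = 101), lib)
an  <- analyze_screen(scr)
summary(an)
head(an$transient_hits)
plot(an, "population")
plot(an, "zfactor")
```

## Known limitations

The analysis assumes a common uniform grid across wells after
interpolation and a 96-well geometry (other geometries are possible in
code but untested). Plate-wise z-scoring removes additive and
multiplicative plate effects but not spatial within-plate gradients
(no B-score/median-polish correction, by design). The supplementary
reproduction helper expects the original published tables as CSV
exports and is inert without them.
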