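---
title: "Models and methods behind chronocline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronocline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chronocline)
```

chronocline analyses chronobiological experiments on fly strains sampled
along a latitudinal cline: photoperiodic diapause assays, DAM locomotor
recordings, immunostaining time courses and confocal ROI quantification.
This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate — i.e. what a green test suite does and does not establish.

## The photoperiodic response model

Diapause incidence at night length $NL$ (hours) is modelled as

$$P(NL) = \frac{d}{1 + e^{-b\,(NL - e)}},$$

a three-parameter logistic dose-response curve with lower bound fixed at
0, upper asymptote $d \in (0,1]$, steepness $b > 0$ (per hour) and
inflection point $e$ (the ED50, hours). The asymptote is left free
because some mild-climate strains plateau below 100% diapause; the lower
bound is pinned because fully reproductive populations at long
photoperiods show essentially no diapause. Counts are treated as
binomial per assay point, independently across flies — no
overdispersion term, since published diapause panels report simple
proportions.

**Critical night length.** Two readings of "50%" exist and coincide only
when $d = 1$: the curve's inflection (ED50, 50% *of the asymptote*) and
the absolute 50% crossing of the population. `critical_night_length()`
returns the absolute crossing, found by root-finding on the fitted curve
(tolerance $10^{-10}$ h) and cross-checked in the tests against the
closed form $e - \log(2d-1)/b$; it is undefined when $d \le 0.5$. Both
the ED50 and the CNL are kept on the fit object and the print method
flags any discrepancy, so the inflection-point reading is never silently
substituted.

**Fitting.** Maximum likelihood by bounded quasi-Newton (L-BFGS-B) with
an analytic gradient, from five starts whose ED50 guesses span the
night-length range and whose slope guesses cover 0.5–5 per hour. Box
bounds: $d \in [10^{-4}, 1]$, $b \in [10^{-3}, 50]$, $e$ within the
night-length range $\pm 24$ h. Because the optimum frequently sits on
the $d = 1$ boundary, where L-BFGS-B's line search can terminate with a
non-zero status despite having converged, a fit whose status is abnormal
is restarted once and then accepted iff the projected gradient (feasible
directions only) vanishes — a KKT check rather than trust in the status
code. Complete separation (all-0/all-1 responses or a perfect step) is
flagged; such slopes are reported but not interpretable. CNL confidence
intervals come from a seeded parametric bootstrap (binomial resampling
at the fitted curve, warm-started refits, percentile interval; if more
than 20% of refits fail the basic interval is substituted with a
warning).

## Sleep, profiles and peak phases

**Sleep** is the standard single-beam DAM convention: a minute is
immobile iff its beam count is zero, and a maximal run of at least 5
immobile minutes is sleep. Light-phase sleep divides the asleep-while
lights-on minutes by the number of analysed days.

**Daily profiles** average each fly over its analysed LD days (the last
5 of the recording, aligned on lights-on so days are biological days),
then across flies, then smooth with a centred 11-min moving average.
The wrap at the day boundary is circular, because the profile is a daily
cycle; this is the one place the package departs from a plain
convolution, and it preserves constants exactly.

**Peak detection** follows the double-plot algorithm: the 1440-bin
profile is duplicated to 2880 bins, loess-smoothed (span 0.02, degree
2), and the peaks are the points where the smoothed curve meets its own
11-point rolling-maximum envelope (equality within $10^{-9}$; contiguous
hits merge to their midpoint). The published description of this
procedure covers the evening peak; the package applies the identical
algorithm to the morning peak, reading the method symmetrically.
Candidates are then assigned within windows that the source method
leaves unstated — a design choice made here once: morning
$[L_{ON} - 2\,h, L_{ON} + 6\,h]$, evening $[L_{OFF} - 8\,h, L_{OFF} +
1\,h]$, chosen to bracket the observed range of entrained phenotypes
under long photoperiods. Within a window the candidate nearest the
light transition wins; ties break by greater smoothed height, then
earlier time. A winning evening candidate within 15 min *after*
lights-off is classified as the clock-independent startle response, the
estimate is flagged `masked`, and no evening peak is reported — this
reproduces the situation where a prominent lights-off spike makes the
true evening peak undeterminable.

## Rhythmicity: Lomb–Scargle with an analytic false-alarm level

Per-minute DD counts are summed into 10-min bins (variance
stabilization; standard DAM practice) and the variance-normalized
Lomb–Scargle periodogram is evaluated on a 14–34 h period grid in 0.1 h
steps — wide enough to bracket both circadian periods and the 12 h
components seen under long photoperiods, without extending over multiple
octaves. A fly is rhythmic iff the maximal power exceeds the threshold
solving $\mathrm{FAP}(z) = \alpha$ (default 0.05).

The false-alarm probability uses Baluev's aliasing-free approximation
for the maximum over a frequency band,
$\mathrm{FAP}(z) = 1 - (1 - e^{-z})\,e^{-\tau(z)}$ with
$\tau(z) = W e^{-z} \sqrt{z}$ and effective bandwidth
$W = \Delta f \sqrt{4\pi\,\mathrm{var}(t)}$. The naive alternative —
counting independent Fourier frequencies in the band — was measured
during development to mis-calibrate the test (a 9.3% type-I rate at
$\alpha = 0.05$ on 1000 simulated arrhythmic flies) because maximizing
over an oversampled grid makes more effective trials than the Fourier
count; Baluev's correction restores the rate to 4.0%, and the test
suite re-measures this calibration. Degenerate inputs are explicit:
constant (e.g. all-zero) series are classified arrhythmic with a
warning, and segments shorter than 3 days are refused.

## The JTK-style cycling test

Staining series are first averaged per brain (cells within a brain are
pseudo-replicates), then compared against cosine references of the
tested period (24 h or 12 h) at every phase lag on the sampling grid —
the minimal reading of testing "in the 24 h / 12 h range". For each lag
the Jonckheere–Terpstra statistic counts concordant pairs across groups
ordered by the reference value; this is the Kendall-correlation reading
of the JTK procedure. The one-sided upper-tail p-value is computed
**exactly** for tie-free data up to $n = 40$ observations, by convolving
Mann–Whitney null distributions obtained from Gaussian-binomial
coefficients (plain $O(n^2)$ polynomial arithmetic, no FFT, so
tail probabilities of $10^{-12}$ remain exact; the null depends only on
the group sizes and is memoized). The exactness cutoff is 40 rather
than a smaller value because typical designs — 8 timepoints × 3 brains
= 24 observations — fall in this range, and the tie-corrected normal
approximation need not match a permutation oracle to Monte-Carlo
accuracy there. Data with ties, or longer series, use the tie-corrected
normal approximation with continuity correction. The reported p-value
is the minimum over lags, Bonferroni-multiplied by the lag count
(matching the published JTK adjustment); constant series return $p = 1$
with an undefined $\tau$.

## Group comparisons

The two-group path is gated: Shapiro–Wilk on each group and a
median-centred Levene (Brown–Forsythe) test on the pair; if all three
p-values are ≥ 0.05 an equal-variance t-test is used, otherwise the
Wilcoxon rank-sum test. Constant groups (where Shapiro is undefined)
fall to the nonparametric branch with a warning. More than two groups:
Kruskal–Wallis, pairwise Wilcoxon with Holm adjustment, and a compact
letter display at 0.05 built by insert-and-absorb.

## The synthetic-data generator

The generator defines the package's "stated world"; published work in
this area provides no generative model, so the choices are made here and
documented once:

* **Activity.** Per-minute counts are Poisson with rate
  $\lambda(t) = \beta\,(1 + s(t))$, where the daily shape $s$ holds
  Gaussian morning and evening bumps (amplitudes in multiples of the
  baseline $\beta$, SD 60 min) anchored to lights-on/lights-off, minus a
  Gaussian siesta trough centred mid-light-phase (SD one fifth of the
  photoperiod). Defaults — $\beta = 2$ counts/min, bump amplitude 3,
  siesta depth 0.6 — give peak-to-trough ratios a DAM user would
  recognise. An optional sharp spike 5 min after lights-off (SD 5 min)
  emulates the startle response of southern strains.
* **Free run.** In DD a fly drawn rhythmic (probability
  `rhythmic_fraction`) continues the same waveform on a
  `free_run_period` time base with its amplitude halving every
  `damping_halflife` days — damping as a continuum rather than a binary
  switch. Arrhythmic flies are flat Poisson. Note a consequence the
  tests respect: a strongly damped fly still carries its full waveform
  through the first DD day, so very fast damping does not guarantee an
  "arrhythmic" call from a 9-day periodogram when bump amplitudes are
  large.
* **Diapause.** Counts are binomial draws from the logistic response
  above; no overdispersion.
* **Staining.** Mesor plus 24 h and 12 h cosines with Gaussian noise,
  independent per brain (and per cell when cells are simulated).
* **Images.** Piecewise-constant stacks: disc somata with per-plane
  intensity profiles, an optional terminal mask, constant background —
  every ground-truth quantity recorded in a sidecar, enabling exactness
  (not just closeness) tests.

What the generator does **not** emulate: inter-fly variance structure
beyond Poisson noise (real northern strains are noisier between
individuals than any Poisson model), activity bout structure and
ultradian rhythms, temperature effects, mortality, assay-to-assay batch
effects, and optical artefacts (noise, bleed-through beyond a constant
ratio, z-attenuation). A green recovery test therefore establishes that
the estimators are correct and calibrated *under this world*, not that
real data meet the model's assumptions.

**Seeding.** Every generator takes an explicit integer seed; the
pipeline derives per-stage seeds from one master seed by fixed offsets
(kept below $2^{31}$), and generators restore the caller's RNG state, so
the whole simulate-and-analyse path is bit-reproducible.

## Degenerate inputs and numerical conventions

* DAM files: strict 42-column layout, strict 1-min monotone timestamps
  (finer bins are aggregated by summation); malformed rows are errors
  naming the line, non-valid status rows are flagged, flies with zero
  counts over their final 24 h are dropped as dead, with a message.
* Background subtraction in imaging clips negative values to 0 by
  default (grey values are non-negative); a flag disables clipping.
  When no background value is supplied, a same-shape ROI translated by
  10 px (first in-bounds, non-overlapping axis-aligned direction) is
  used and its coordinates are kept on the result for audit.
* "Brightest focal plane" is searched within ±3 planes of the seed
  voxel's plane.
* Ties at the 10th-brightest pixel include all tied pixels and
  renormalize over the count actually used, with a message.
* Bootstrap intervals, loess, optim and all tests are deterministic
  given the seed; no parallelism.

## Known limitations

* The PPRC fit reports no Wald covariance; uncertainty is bootstrap-only
  by design (the likelihood is typically boundary-constrained at
  $d = 1$, where Wald intervals misbehave).
* The JTK lag grid equals the sampling grid; sub-interval phase
  resolution is not attempted, and the optional period-band scan is
  deliberately excluded from the default analysis.
* Peak assignment windows are fixed design constants; profiles whose
  morning activity genuinely precedes lights-on by more than 2 h (or
  evening activity trailing lights-off by more than 1 h) will report an
  absent peak rather than search outside the windows.
* The imaging module assumes registered channels from a single
  acquisition; no registration is performed.
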