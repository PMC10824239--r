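---
title: "Methods: OJIP transient analysis, the JIP test, and threshold detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OJIP transient analysis, the JIP test, and threshold detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipr)
library(dplyr)
```

## The measurement and the model

A dark-adapted leaf exposed to saturating light emits chlorophyll-a
fluorescence that rises from a minimal level O (measured at 20 µs, when
all photosystem II reaction centres are open) through two inflections J
(2 ms) and I (30 ms) to a maximum P (Fm, all centres closed).  This
polyphasic OJIP rise, sampled on a log-dense time grid from tens of
microseconds to about a second, carries enough kinetic information to
estimate how absorbed light energy is partitioned between photochemistry,
electron transport and heat — the JIP test.

`ojipr` implements the complete chain for a graded root-cutting stress
experiment: curves arrive as long tables (one row per time point, labelled
with plant, root-cutting-ratio group, replicate, day, clock time and
duplicate-measurement index), duplicates are averaged pointwise *before*
any parameter is computed, cardinal points are interpolated, the JIP
parameter system is evaluated per leaf, and groups are compared against
the control with Dunnett's many-to-one procedure.

### Cardinal-point extraction

F0, F300µs, FJ and FI are obtained by interpolation **linear in
log10(time)** between the bracketing samples (exact sample values when a
mark coincides with a grid point).  OJIP curves are conventionally
displayed, and are close to piecewise linear, on a logarithmic time axis;
linear-in-time interpolation would systematically overshoot on the steep
O–J rise.  Fm is the global maximum of the sampled curve (the P step), not
a plateau fit: with about a second of recording, the rise has saturated
and a maximum is robust; an instrument-reported Fm is not available in the
table dialect, so the curve maximum is used throughout and any sensitivity
to that choice can be probed by truncating the grid.

A curve is flagged *flat* when its variable fluorescence is small,
`Fm − F0 < ε · F0` with ε = 0.05 by default.  This operationalises the
"almost horizontal" midday curves of severely stressed leaves; for such
curves the ratio parameters are meaningless and are reported as
flagged-missing rather than as numbers.  ε is configurable (`eps_flat`)
everywhere it matters.  Note that with multiplicative measurement noise of
a few percent, the max-over-samples Fm estimator inflates the measured
variable fluorescence of a truly flat curve, so near-flat noisy curves may
escape the flag; their kinetic ratios are then caught by the degeneracy
guard below.

### The JIP parameter system

With VJ = (FJ − F0)/(Fm − F0) and M0 = 4(F300 − F0)/(Fm − F0):

* specific (per active reaction centre) fluxes: TR0/RC = M0/VJ,
  ET0/RC = (M0/VJ)(1 − VJ), ABS/RC = (M0/VJ)/(1 − F0/Fm),
  DI0/RC = ABS/RC − TR0/RC;
* yields: φP0 = TR0/ABS = 1 − F0/Fm = Fv/Fm, ψ0 = ET0/TR0 = 1 − VJ,
  φE0 = ET0/ABS = φP0·ψ0;
* the absorption-based performance index
  PI_abs = (RC/ABS)·[φP0/(1 − φP0)]·[ψ0/(1 − ψ0)], with
  RC/ABS = 1/(ABS/RC).  Sources differ on which performance index a study
  means when it just says "PI"; the absorption-based PI_abs above is the
  established default and is what this package computes (the total
  performance index, which additionally uses the I step, is out of scope).
* phenomenological (per excited cross-section at the O step) fluxes, using
  the F0 approximation ABS/CS0 = F0: TR0/CS0 = φP0·F0, ET0/CS0 = φE0·F0,
  DI0/CS0 = F0 − TR0/CS0, and reaction-centre densities
  RC/CS0 = F0/(ABS/RC), RC/CSm = Fm/(ABS/RC).

Degenerate inputs never propagate as infinities.  VJ at 0 or 1, or a
non-positive initial slope M0 (which happens when noise dominates a
near-flat curve), flags the per-RC block as missing; the VJ = 1 limit
keeps its finite values TR0/RC = M0, ET0/RC = 0.  Group statistics then
exclude flagged values explicitly and report the exclusion counts.

The normalized complementary area Sm = ∫(Fm − F(t))dt/(Fm − F0), taken
from the 20 µs mark to the time of Fm with the trapezoidal rule in linear
time, is reported in **milliseconds**: for a single-exponential rise with
time constant τ it equals τ, which is also the closed-form oracle used in
the tests.  The lower limit is the 20 µs mark (not the first sample) so
that Sm is independent of how much pre-O baseline a grid happens to
include.

### Energy pipeline models

Per group, the four per-CS0 fluxes are averaged arithmetically over
non-flagged leaves, and the active reaction-centre fraction is the group's
mean RC/CS0 referenced to the control group's mean, clipped to [0, 1] and
discretised into 12 display circles by default (the circle count is purely
visual granularity).  Parameters are averaged, **never** curves: the JIP
map is nonlinear, so the parameters of an average curve are not the
average parameters — the test suite contains an explicit counterexample.
By default all clock times are pooled; pass a filtered table to stratify.

## Group statistics and the threshold

Each parameter is compared across groups by one-way ANOVA followed by
two-sided Dunnett many-to-one comparisons against the control
(single-step multivariate-t adjustment, via `multcomp`), with the
four-tier star convention (0.05, 0.005, 0.0005, 0.0001).  Two-sided tests
are required because stress moves parameters in both directions (Fm down,
M0 and DI0/CS up).  Leaf-level averaged measurements are treated as
independent observations — the classical pooled design of this kind of
field study; a mixed-model treatment of plant and day effects is a
deliberate non-goal.  The classical procedure assumes homogeneous
variances; a warning is emitted when group variances differ more than
fourfold, which routinely happens when a flattened midday group sits next
to healthy ones.  The multivariate-t p-values are evaluated under a fixed
internal RNG substream (restored afterwards), so identical inputs always
give identical p-values regardless of row order or caller RNG state.

`detect_threshold_rcr()` answers "at which root-cutting ratio does the
photosynthetic machinery begin to change?" with a persistence rule: the
smallest RCR at which **every** core parameter (default Fm, Fv/Fm,
PI_abs) is significant there *and at every larger ratio*.  The rule is
deliberately robust to isolated spurious stars and to the late-afternoon
"self-recovery" of intermediate groups, which makes significance
non-monotone in time-stratified data (a warning reports non-monotone
patterns).  With stratified results the per-stratum thresholds are
combined by taking the smallest — the earliest ratio at which *any*
measurement window shows a persistent change of the whole core set.  This
choice matters: pooling all clock times into one test inflates the
residual variance with the (physically real) midday collapse of the
severely stressed groups and can mask a clear morning signal at moderate
stress; stratification plus the minimum rule keeps the detector sensitive
without touching the error calibration under the null (where no stratum
produces a persistent full-set signal).

## The synthetic experiment

No public numeric transient data exist for this design, so the package
ships a generator that emulates the study conditions: 7 RCR groups
(0/10/20/30/50/75/100 %, the treated ones realised as cutting angles of
36–270° plus full removal), 3 replicate plants, 5 clock times (9:00–17:00),
2 days, 2 measurements per leaf — 420 curves, 70 log-spaced samples each
over [20 µs, 1 s].

Each noise-free curve is a logistic mixture in log time,
`F(t) = F0 · (1 + A · Σ w_k [s((log10 t − log10 τ_k)/σ_k) − s_k(20 µs)])`,
one component per OJIP phase (τ = 0.4, 8, 80 ms; weights 0.5/0.3/0.2).
Anchoring at 20 µs makes F(20 µs) = F0 exactly, so amplitude stress leaves
F0 untouched — mirroring the robustness of the O step relative to J/I/P.
The control amplitude is solved in closed form so that control Fv/Fm is
exactly the configured 0.82 (the conventional healthy dark-adapted value
is above 0.8).  All magnitudes are package defaults documented as
synthetic; none are field measurements.

Stress enters multiplicatively on A: depression d(r) = 0 up to 30 % RCR
and 0.25/0.45/0.65 at 50/75/100 % (onset at 50 %, inside the plausible
30–50 % band, so the threshold detector has a defined ground truth); a
diurnal modulation with a midday minimum (0.94 at 13:00); near-complete
flattening (×0.008) of the 75 % group at 13:00/15:00 and the 100 % group
at 13:00–17:00, partial flattening (×0.6) of the 50 % group at
13:00/15:00; a 17:00 recovery shrinking d by ×0.2 (50 %) and ×0.6 (75 %)
but not at 100 %; and an inflated O–J weight (0.7) at 100 % RCR, raising
VJ.  The recovery coefficients are free parameters of the emulation —
the underlying field phenomenon is qualitative — and are exposed in the
configuration for sensitivity analysis.

Noise is per-point multiplicative lognormal (σ = 0.03) plus small
per-plant and per-day lognormal amplitude effects (σ = 0.01 each).  The
per-plant and per-day scales are kept below the measurement noise because
the analysis pools leaves as independent units: with only three plants per
group, a large plant-level random effect would make the pooled Dunnett
comparisons anticonservative by design rather than by defect.  The
generator emulates the *design and phenomenology* of such an experiment,
not leaf optics: it does not model detector nonlinearity, connectivity
(L/K-bands), state transitions, or genuine within-plant correlation
structure, so passing tests demonstrate the pipeline's correctness on
curves of realistic shape, not biological validity on real leaves.

Randomness is reproducible at curve granularity: every curve, plant and
day draws from a substream seeded by hashing its design labels together
with the root seed, so regeneration is byte-identical and subsetting the
design never changes the curves that remain.

## Numerical choices and problem sizes

* Interpolation and Sm integration are deterministic; ties in the curve
  maximum resolve to the earliest sample.
* Identity tests run over 10⁴ randomized valid cardinal-point sets at
  10⁻¹⁰ relative tolerance.
* The null-calibration suite runs 1,000 simulated 7-group experiments
  (n = 6 per group, the size of one clock-time stratum) and requires the
  family-wise tier-`*` rate in [0.03, 0.07].
* The recovery suite runs 200 full synthetic experiments (420 curves
  each) through the entire pipeline and requires the modal detected
  threshold to equal the configured 50 % onset in at least 80 % of runs.
  These sizes keep the whole suite comfortably within a half-hour on a
  single core while leaving the Monte-Carlo error well below the margins
  being asserted.

## Known limitations

* The flat-curve flag is a threshold rule, not an inference; near-flat
  noisy curves can pass it and are instead caught (partially) by the
  kinetic degeneracy guard.
* Classical equal-variance Dunnett is knowingly applied to heteroscedastic
  strata (with a warning); a robust or mixed-effects alternative is out of
  scope.
* I-step-based parameters (VI, ψRE0, PI_total) and connectivity analyses
  are not computed.
* The threshold detector's granularity is the design's RCR grid; it cannot
  localise a change point between tested ratios.
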