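---
title: "Methods: trace-level analysis of two-photon calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace-level analysis of two-photon calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciumflow)
```

`calciumflow` implements the trace-level analyses used to characterize
behavioral-state modulation and visual tuning of neurons recorded with
two-photon calcium imaging in mouse primary visual cortex (V1), together
with quantification of retrograde monosynaptic rabies tracing and a
hierarchical bootstrap for nested group comparisons.  The pipeline starts
where ROI extraction (e.g. Suite2p) ends: its inputs are somatic and
neuropil fluorescence traces, locomotion and pupil series, a trial schedule,
and — for tracing — a table of detected cells.  Because no recordings ship
with the package, a seeded synthetic-session generator reproduces the
statistical structure the analyses assume, and every stage is validated
against that ground truth.

## Preprocessing of fluorescence traces

Somatic traces are corrected for neuropil contamination by linear unmixing,
$F = F_{soma} - r\,F_{neuropil}$, with $r = 0.7$ for GCaMP6f/GCaMP7s and
$r = 0.8$ for jGCaMP8m (overridable).  The baseline $F_0(t)$ is the 30th
percentile of $F$ over a 150 s moving window; the window is *centred* and
truncated at the trace edges.  Centring avoids the phase lag a causal window
would introduce into $F_0$; percentiles interpolate linearly between order
statistics (R's default type-7 rule), so the oracle check in the test suite
is exact.  $\mathrm{d}F/F_0 = (F - F_0)/F_0$ requires $F_0 > 0$ everywhere —
a nonpositive baseline raises an error rather than being clipped, which in
practice means synthetic fluorescence must carry a positive offset.

Standardized $\mathrm{d}F/F_0$ subtracts the median and divides by the
standard deviation.  Two conventions are fixed package-wide: the *median* is
the centring statistic (the mean appears in one description of the
inclusion rule, but the explicit preprocessing formula uses the median, and
one convention has to win), and all standard deviations are *sample* SDs
(denominator $n-1$).  An ROI enters correlation analyses only if its
standardized trace reaches 3 at least once (inclusive threshold): a trace
with no transient three SDs above its median carries no usable signal.

Correlation analyses run at 5 Hz: traces are linearly interpolated onto a
10 Hz grid, smoothed with a centred 5-point moving average (edge windows
truncated), and decimated by 2.  The chain's frequency response is analytic
— a 0.1 Hz sinusoid passes with gain
$\sin(5\pi f/10)/(5\sin(\pi f/10)) \approx 0.996$ — and the test suite
verifies the implementation against both that gain and a brute-force
oracle.

## Behavior conditioning

Locomotion voltage is convolved with a normalized kernel, mean-binned to
30 Hz and scaled to cm/s.  Blink detection operates on the z-scored blink
trace: Hanning smoothing (default 0.26 s), differentiation, and velocity
threshold crossings (default 4 z/s) mark onsets (fast negative velocity) and
offsets (fast positive velocity); intervals grow by a 0.1 s buffer on each
side and merge when closer than 0.3 s.  These four defaults are conventions,
not published values; they are plain config parameters.  Gaps left by
removing blink samples are filled with a cubic spline through the remaining
samples — non-blink samples are never altered, and edge gaps that force
extrapolation are flagged.

## Behavioral-state analysis

Frames are stationary when speed $\le$ 1 cm/s and running above it (the
boundary is stationary, matching the rule's wording); sessions where one
state never occurs are rejected rather than silently summarized.  Per-neuron
state means are reported as run minus stationary.

The association between activity and locomotion is the Pearson correlogram
of the two 5 Hz series over lags up to $\pm$10 s (a convention; the
correlogram window is not prescribed anywhere).  Positive lag means activity
follows speed.  Significance of the zero-lag coefficient comes from a
shuffle test with 1000 shuffles and the add-one estimator
$p = (1 + \#\{|r_{shuf}| \ge |r_0|\})/(1 + N)$, so $p$ is never zero.  The
peak correlation and its lag are reported only for significant neurons.

**Choice of null.**  Two shuffles are implemented: a circular shift of one
series (default) and a full value permutation.  The value permutation
destroys all autocorrelation, but the 5 Hz chain itself guarantees
autocorrelation: a 5-point average decimated by 2 leaves adjacent output
samples sharing 3 of 5 inputs, i.e. lag-1 autocorrelation 0.6 and lag-2
autocorrelation 0.2 even for white noise.  For two independent series the
zero-lag coefficient has variance
$\tfrac{1}{n}\sum_k \rho_x(k)\rho_y(k)$; against a slowly varying speed
trace the smoothing alone inflates that variance by
$\approx 1 + 2(0.6) + 2(0.2) = 2.6$ relative to the permutation null,
turning a nominal 5% test into a $\approx$20% one before any
calcium-kernel autocorrelation is counted.  A circular shift preserves each
series' autocorrelation while breaking their alignment, and the test suite
verifies its calibration both on white-noise pairs and on full synthetic
sessions with uncoupled neurons.  The value permutation remains available
(`null = "permute"`) for comparison.

Pairwise synchrony applies the same zero-lag statistic and null to every
unordered neuron pair within a field of view, reusing one set of shuffles
across pairs.

## Orientation tuning

A trial response is the mean standardized $\mathrm{d}F/F_0$ over the grating
window minus the mean over the 0.5 s immediately before onset; windows are
half-open in frames, $[\lfloor t_{on} f_s \rfloor, \lfloor t_{off} f_s
\rfloor)$.  A neuron is *responsive* if its response exceeds three times the
SD of that trial's baseline window in at least two trials; a zero-SD
baseline makes any positive response count.

Mean responses per orientation are min–max normalized before the
selectivity indices, so negative standardized responses cannot corrupt
them.  The global orientation selectivity index is the modulus of the
doubled-angle vector sum,
$\mathrm{gOSI} = \left|\sum_\theta \bar R(\theta) e^{2i\theta}\right| /
\sum_\theta \bar R(\theta)$ — the modulus is the only reading that yields a
real number in $[0,1]$.  The direction selectivity index is
$(R_{pref} - R_{null})/(R_{pref} + R_{null})$ with $R_{null}$ at the
direction 180° opposite the argmax (ties break to the smallest angle).
SNR per orientation is the squared mean response over the sample SD of
repetitions, averaged across orientations with zero-SD orientations
excluded.  Tuning curves are also reported circularly shifted so the
preferred bin sits at 90° ("pseudo-90°").

Signal correlation between two neurons is the Pearson correlation of their
mean tuning curves computed on disjoint halves of the repetitions (the
extra repetition of an odd count goes to the first neuron; one seeded split
by default), which removes shared trial-by-trial noise.  Noise correlation
is the mean across orientations of the repetition-vector correlation at a
fixed orientation.

One validation subtlety: the generator-fidelity check that gOSI grows with
the ground-truth von Mises concentration $\kappa$ evaluates gOSI on the raw
(nonnegative, baseline-cancelled) mean responses.  Min–max normalization is
degenerate at $\kappa = 0$ — the curve is exactly flat — and near $\kappa =
0$ it amplifies numerical dust to the full $[0,1]$ range, so the
monotonicity property is only well posed on the raw curve.  Measured-data
metrics keep the normalized convention throughout.

## Contrast tuning

Trials are labelled stationary or running by the mean speed over their
stimulus window (boundary 1 cm/s inclusive to stationary).  The contrast
response curve pools orientations at each of the six contrasts
(5–80%); blank (0%) trials are averaged separately and never enter the
curve.  The log-scale centre of mass is
$\mathrm{cCOM} = \exp\!\big(\sum_c w_c \ln c / \sum_c w_c\big)$ with
$w_c = \max(\bar R_c, 0)$: a centre of mass needs nonnegative weights, and
blanks are excluded because $\ln 0$ is undefined.  The preference class is
taken from the argmax of the contrast curve (ties to the lower contrast):
5–10% is *low*, 60–80% *high*, anything else *other*.  The classification
rule behind published low/high ratios is not spelled out anywhere; argmax is
the default here, and a cCOM-band classifier would be a drop-in alternative.

## Hierarchical bootstrap

Group comparisons respect the animal → neuron (→ trial) nesting: each
replicate resamples animals with replacement, then units within each chosen
animal (then trials, when trial-level data are supplied), and the group
statistic (default mean) is computed on the pooled resampled values.  The
two-sided p-value is the sign-crossing probability of the difference
distribution with add-one smoothing, with ties at zero counted on both
sides so degenerate data give $p = 1$; confidence intervals are percentile
intervals.

With few animals the naive cluster bootstrap understates between-animal
variance by $(A-1)/A$ — for $A = 5$ a 20% deficit — which inflates the
false-positive rate.  Each replicate therefore draws $A - 1$ animals, the
classical $m = n - 1$ correction that makes the resampled mean's variance
match the sampling variance of the observed mean; the naive scheme remains
available (`animal_draws = "A"`).  The acceptance suite checks calibration
on simulated null data (5 animals × 20 neurons per group, between-animal SD
equal to within-animal SD) and, on the same data, that a pooled t-test
over-rejects — the anti-conservatism the method exists to avoid.  BCa and
studentized variants are deliberately out of scope, and linear mixed models
are delegated to standard tooling rather than reimplemented.

## Rabies tracing quantification

In a traced-cell table a *starter* is GFP+/mCherry+ and an *input* is
mCherry+/GFP−.  Input fractions are percentages of all input cells per
region and hemisphere; starters are excluded from the denominator (the
cleaner reading of "presynaptic inputs"; a flag restores inclusion), and a
region is *reported* only above a strict 1% of inputs.  Starter layer
distributions normalize over starters; local layer fractions restrict to
ipsilateral input cells of the injection-site region (default `VISp`,
Allen CCFv3 acronyms) and normalize over that local count.  Image
registration and cell detection are upstream of this package; the table is
the interface.

## The synthetic-session generator

Each simulated neuron fires Poisson events at a rate
$\lambda(t) = b\,g(t) + s\,v(t) + G\,f_{ori}(\theta_t)\,f_{con}(c_t)$,
where $b$ is the baseline rate, $g(t)$ the running gain (active above
1 cm/s), $s$ the speed coupling against speed $v(t)$, and the visual term
multiplies a peak-normalized von Mises curve on the doubled angle (direction
asymmetry optional) by a Naka–Rushton contrast response
$c^n/(c^n + c_{50}^n)$ — or its reflection $1 - NR$ for
low-contrast-preferring neurons.  Events convolve with a single-exponential
calcium kernel (decay 1 s, GCaMP-like; indicator kinetics beyond this are
out of scope), scale by 20 a.u. per event over a 100 a.u. somatic offset,
and mix with a shared low-pass neuropil signal (offset 30 a.u., SD 3 a.u.,
2 s time constant, weight 0.7) plus white measurement noise (SD 4 a.u.,
i.e. roughly a fifth of a transient peak — ordinary imaging quality).  A
`deterministic` switch replaces every draw by its expectation for
noise-free ground-truth checks.

Locomotion is a two-state semi-Markov process: exponential stationary and
running bouts (means 20 s and 10 s) with lognormal bout speeds (median
5 cm/s), smoothed over 0.5 s; real running-bout statistics for head-fixed
mice are not published alongside the analyses, so these are conventions
chosen to sample both states well within a 730 s session.  The pupil trace
is a slow AR(1) signal with Poisson-timed dropout pulses whose true
intervals are returned for validating blink detection.  Trial schedules
reproduce the recording protocols: 730 s gray-screen spontaneous sessions;
6 s orientation trials (1 s gray, 2 s grating at 80% contrast, 3 s gray)
over 12 directions 30° apart; 3 s contrast trials (0.8 s gray, 2 s grating,
0.2 s gray) crossing six contrasts with 8 directions, 15 repeats, and one
randomly placed blank per 20 trials.  Traced-cell tables sample regions,
layers and hemispheres multinomially from a stated spec.

Default populations encode the phenomena under test: locomotion-coupled
neurons (0.3 events/s per cm/s over a 0.1 events/s baseline) against
near-silent uncoupled neurons (0.02 events/s), visually driven neurons
(peak 5 events/s) against non-visual ones.  The near-silent choice matters
twice: it models the genuinely sparse firing of many cortical neurons, and
it puts uncoupled traces in the noise-dominated, low-autocorrelation regime
in which a shuffle null is meaningful at all.  All randomness flows through
one seeded generator per call with the caller's RNG state restored, so
fixed seeds reproduce every output bit-identically.

What the generator does *not* emulate bounds what passing tests show:
there are no motion or z-drift artifacts, no eye movements coupled to the
stimulus, no shared variability beyond the common neuropil (so measured
noise correlations centre on zero by construction), linear indicator
response, and stylized bout statistics.  Recovery results on synthetic
sessions demonstrate that the implementations compute their definitions
correctly and that the inference is calibrated under the generator's
assumptions — not that real V1 data satisfy those assumptions.

## Sessions, results and determinism

A session container holds fluorescence, behavior, schedule, optional ground
truth and metadata; it persists to a directory (arrays as RDS, metadata as
JSON, trial table as CSV) with a bit-exact round trip.  `run_protocol()`
chains preprocessing and the protocol's analyses, writes CSV tables plus a
JSON summary, refuses to overwrite results unless asked, and — given the
same config and seed — reproduces every output file byte for byte.  Trial
windows are half-open in seconds and convert to frames by
$\lfloor t \cdot f_s \rfloor$; each trace stores its own rate.

Validation problem sizes are chosen to exercise the statistics at useful
power while keeping the full suite quick: 300–500 white-noise pairs for
shuffle-test calibration, 40-neuron/730 s sessions for coupling recovery,
80–220 neuron sessions for tuning and contrast recovery, 100–200 simulated
datasets (1000 bootstrap replicates each) for bootstrap calibration and
power, and 5000-cell tables for tracing round trips.

## Known limitations

* The responsiveness filter is permissive for spontaneously active neurons:
  a couple of chance transients inside stimulus windows can flag a neuron
  with substantial baseline firing.  This mirrors the rule's behaviour on
  real interneuron data, where nearly all recorded cells pass it.
* The circular-shift null assumes approximate stationarity within a
  session; strongly non-stationary sessions (e.g. a single run bout at the
  very end) weaken it.
* cCOM compresses a six-point curve to one number; flat or multi-peaked
  contrast curves are better read from the curve itself.
* The hierarchical bootstrap is approximate for very few animals; with one
  animal per group it degrades (with a warning) to unit-level resampling
  and cannot represent between-animal uncertainty.
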