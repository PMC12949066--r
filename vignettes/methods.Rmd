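---
title: "Cardiac synchrony in small groups: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac synchrony in small groups: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When people interact, their autonomic nervous systems can fall into step:
moment-to-moment fluctuations of heart rate become correlated across
individuals. This *physiological synchrony* is studied as a marker of social
connection — in classrooms, between friends, within families. `dyadsync`
implements a complete analysis chain for studies in which small groups
(here, 4–6 classmates) perform shared tasks while each member wears a
beat-interval (R-R) logger:

1. artifact correction and uniform resampling of the R-R series;
2. individual parasympathetic tone via windowed high-frequency heart rate
   variability (HF HRV);
3. dyadic synchrony via band-wise cross-wavelet power of paired heart-rate
   trajectories;
4. questionnaire-derived dyadic measures (friendship, closeness, liking,
   affect coherence, empathic accuracy);
5. multilevel models with AR(1) residuals linking synchrony to those
   measures; and
6. a fully seeded synthetic-cohort generator that plants known coupling
   effects so the whole chain can be validated without any participant data.

## Preprocessing the beat series

Chest-strap loggers export one interval per beat (ms). Three rules clean
the series, in this order:

- **Outlier rule (30 %).** A beat whose interval differs from the *last
  retained* interval by strictly more than 30 % is removed. Comparing
  against the last retained beat rather than the immediate predecessor
  matters: after a single spike, the following normal beat would otherwise
  look deviant too, and a run of artifacts would partially survive. The
  boundary is strict (`> 0.30` removed, exactly 30 % kept). Outliers are
  *removed*, not replaced — the resulting holes are handed to the gap rule,
  which keeps the two mechanisms separately testable.
- **Gap rule (2 s).** Any inter-beat gap above 2 s is filled with synthetic
  beats. The interval assigned to each synthetic beat is the linear
  interpolant between the two flanking retained intervals *evaluated at the
  beat's own timestamp*, and each beat is spaced by exactly that interval
  (the implicit equation is linear and solved in closed form). A gap at a
  phase boundary has only one flank and is left unfilled, noted in the
  report.
- **Exclusion rule (10 %).** "Changed data" is defined as removed beats
  plus synthesized beats, divided by the *original* beat count. A recording
  with a changed fraction of 0.10 or more is excluded; 0.0999 is retained.
  The boundary is exact and tested as such.

For the synchrony chain, instantaneous rate (60000 / rr, bpm) is
interpolated to a uniform 1 Hz grid with monotone piecewise-cubic
(Fritsch–Carlson) interpolation — smooth enough for the wavelet stage but
incapable of overshooting the beat-wise values; edges use constant
extrapolation and are flagged invalid. HRV estimation uses its own 4 Hz
tachogram resampling (below): the two rates serve different estimators and
are independently configurable.

## HF heart rate variability

Per subject and task phase, 120-s windows shifted by 60 s (a phase of
length $L$ yields $\lfloor (L-120)/60 \rfloor + 1$ windows). Within each
window the tachogram is resampled at 4 Hz, linearly detrended, Hann
tapered (with power-loss compensation by the mean squared taper), and the
one-sided periodogram is integrated over 0.15–0.4 Hz, boundary bins
weighted by their overlap with the band. Units are ms²; the natural log is
the modelling scale, as usual for HF power, whose distribution is strongly
right-skewed. The estimator choices (detrend, taper, 4 Hz, log) are not
dictated by the analysis design; they follow common HRV toolchain
behaviour and are all exposed as arguments.

The test suite holds this estimator against an independent untapered
periodogram oracle: a pure 0.25 Hz modulation must agree within 10 %, a
0.05 Hz modulation must leak less than 5 % of its own band power into the
HF band, and band power must scale quadratically with modulation
amplitude.

## Cross-wavelet synchrony

Each 1 Hz heart-rate trajectory is transformed with an analytic Morlet
wavelet, centre frequency parameter $\omega_0 = 6$ (the field standard),
12 voices per octave spanning at least 0.031–0.5 Hz. The discrete
transform is defined as
$$W_b(s) = \sum_m x_m \sqrt{\tfrac{dt}{s}}\; \psi_0^{*}\!\big((m-b)\,dt/s\big),
\qquad \psi_0(\eta) = \pi^{-1/4} e^{i\omega_0 \eta} e^{-\eta^2/2},$$
computed via FFT with zero padding to twice the next power of two. One
numerical subtlety is deliberate: at scales whose spectrum touches the
Nyquist frequency, the *sampled* wavelet aliases, so the FFT kernel is the
periodized Gaussian rather than the one-sided continuous one. This makes
the FFT route agree with literal time-domain convolution
(`cwt_morlet_direct()`, the package's own brute-force oracle) to machine
precision, and the acceptance suite requires $10^{-6}$ relative agreement
on 256-sample signals.

Dyadic synchrony is the cross-wavelet power $|W_a W_b^{*}|$ — symmetric in
member order and blind to relative phase, so in-phase and anti-phase
co-oscillation score identically (the analysis deliberately does not
separate the two). Per 20-s non-overlapping interval aligned to phase
start, the maximum power over the interval's time points and over all
frequency bins inside each band (HF 0.125–0.5 Hz, LF 0.031–0.125 Hz) gives
one value per interval per band. Samples outside the cone of influence
(e-folding time $\sqrt{2}s$) are excluded by default; masking, padding and
voice density are configuration, since different upstream toolchains
differ here.

Story series are truncated to 8 minutes (24 intervals) and discussion
series to 10 minutes (30 intervals) so groups of different discussion
lengths contribute equally. Each band is then z-scored against the mean
and SD pooled over *all* dyads, phases and intervals, making 0 "average
synchrony in this sample". Z-scoring is per band: the two bands live on
different raw power scales and are modelled separately. The pooled mean-0 /
SD-1 property is asserted to $10^{-10}$.

## Questionnaire measures

All affect measures use a 3×3 affect grid (valence, arousal ∈ {1,2,3});
the maximal grid distance is $\sqrt{8} \approx 2.83$ and both similarity
measures are re-coded so that larger is closer:

- *affect coherence* of two self-reports:
  $\sqrt8 - \lVert (v_a, r_a) - (v_b, r_b) \rVert_2 \in [0, 2.83]$;
- *empathic accuracy* of one member's estimate of the other's state,
  defined identically on (estimate, actual); the dyadic sum of both
  members' accuracies spans $[0, 5.66]$.

Friendship status comes from name nominations (mutual / one-sided / none;
self-nominations ignored). Closeness is the sum over raters of each
rater's T0/T1 mean on the 0–6 overlapping-circles (IOS) scale, range 0–12.
Liking is eight 1–4 trait items with *boring* and *mean* reverse-coded as
$5-x$, averaged per timepoint (a timepoint with more than two missing
items is dropped), then across T0/T4, then summed over raters (2–8);
Cronbach's alpha is provided for the item battery. Dyadic valence and
arousal are plain sums of the two T1 self-reports (2–6). Likert anchors
are coded 1–4 — the instruments publish labels, not numbers, so the coding
is explicit configuration. Seating relation is derived from circular seat
indices: distance 1 is adjacent, maximal circular distance is across,
anything else non-adjacent; adjacency wins the tie in a triangle.

## Multilevel models

Repeated measures sit inside dyads (or subjects) inside groups. The
package fits, via `nlme`:

- **ICCs** from intercept-only nested random-intercept models, reported as
  each component's percentage of total variance.
- **Covariate screening**: marginal association tests (Pearson for
  numeric, one-way F for categorical), retained at $p < .05$, every
  decision logged. The exact screening test is configuration — designs
  differ here and the package does not pretend otherwise.
- **Structure selection**: a declared nested sequence (null → random
  intercepts → fixed time → random slopes → AR(1)) compared stepwise by
  ML likelihood-ratio tests at $\alpha = .05$; non-converging steps are
  skipped with the predecessor retained.
- **Reported fits**: REML, dummy coding with the references fixed by the
  design (task: baseline for HRV, story for synchrony; friendship: none;
  gender combination: mixed), random intercepts for group and unit, an
  optional random slope for time, and AR(1) residual correlation indexed
  by observation order *within unit and phase* (implemented by giving
  phases distant integer positions, so cross-phase correlation is
  numerically zero). Rank deficiency is an error naming the aliased
  columns rather than silent dropping; the closeness/friendship
  collinearity diagnostic is a refit-with-dropped-term comparison, not
  automation.
- **Marginal R²**: variance of the fixed-effect predictions over the sum
  of fixed, random and residual variances, with an optional drop-one-term
  semi-partial variant; the variance explained per random level relative
  to an intercept-only refit is also available.

Time enters the models as the window/interval index within phase, not
seconds; this is configurable and only changes the slope's units.

## The synthetic cohort

The generator states a world and keeps it fixed:

- groups of 4–6; per-dyad friendship mutual with probability 0.28,
  one-sided 0.14 (the population the package emulates reports ~28 % and
  ~14–16 %); ages ~ N(11.3, 0.7²) years in 10–13, heights ~ N(1.50, 0.08²) m,
  BMI ~ N(18.5, 2.5²);
- phases: 300 s baseline, 540 s story, 660 s discussion — the story and
  discussion exceed their 8/10-minute truncation targets, so truncation
  does real work;
- per subject, an instantaneous-rate process: baseline level
  ~ N(82, 6²) bpm, an RSA sinusoid near 0.25 Hz (±15 % individual jitter,
  amplitude 2.5 bpm), an LF oscillation near 0.1 Hz (amplitude 2 bpm),
  and unit-variance pink noise; beats are emitted by integrate-and-fire
  (a beat whenever the integrated rate accumulates one cycle), which keeps
  intervals positive by construction;
- per dyad, shared band-limited Gaussian drives (LF: 0.05–0.10 Hz, HF:
  0.20–0.30 Hz) added to both members' rates. The LF weight is 0.6 for
  non-friends and 1.15 for mutual friends (one-sided halfway); the HF
  weight is $0.8 + 0.42\,(6 - \text{valence sum})/4$, i.e. grows with the
  dyad's negative affect. These weights were calibrated once, by
  simulation at the 30-group scale, so that the fitted dyadic models
  recover a mutual-friendship LF coefficient near +0.24 z-units and a
  negative HF–valence coefficient near −0.1 — the effect magnitudes the
  design targets — and then frozen. Liking, empathic accuracy and affect
  coherence are generated without any path into the couplings (beyond
  what the modelled variables already carry), making them genuine null
  effects for coverage checks.

What a green end-to-end test establishes: the chain detects planted
band-specific coupling with the right sign and approximately calibrated
intervals under this generative model. What it does not establish:
behaviour under real respiration-driven RSA, movement artifacts beyond
simple spikes/dropouts, non-stationary task effects, or phase-locked (as
opposed to shared-drive) coupling — the generator adds common input rather
than coupling oscillator phases, because cross-wavelet *power* (a
magnitude) is the analysed quantity.

## Numerical choices and degenerate inputs

- Wavelet padding: factor 2 beyond the next power of two; wrap-around
  leakage is below $10^{-6}$ for all supported signal lengths.
- Signals shorter than twice the largest wavelet support are rejected.
- An interval whose band block is fully COI-masked yields `NA`, and a
  pooled SD of zero makes z-scoring an explicit error, not a silent NaN.
- `hf_log` is `NA` for non-positive power (a constant window).
- Exactly-boundary cases are pinned by tests: 30 % deviation kept, 2.0 s
  gap unfilled, changed fraction 0.10 excluded.
- Mixed-model non-convergence is an error in `fit_model` but a logged,
  skipped step in `select_structure`.

## Known limitations

- The AR(1) position trick assumes integer observation indices within
  unit-phase; irregularly timed repeated measures would need a
  continuous-time correlation structure.
- The HRV window validity rule (unfilled gaps covering > 20 % of a
  window) is a pragmatic data-quality gate, not a published standard.
- Group-average versus dyad-pooled friendship rates differ slightly in
  the emulated population (28.06 % vs 28.40 % mutual); the generator uses
  the per-dyad probability 0.28 and makes no attempt to model classroom-
  level heterogeneity in friendship density.
- The models treat dyads as exchangeable and ignore the partial overlap
  of dyads sharing a member; the group-level random effect absorbs part,
  but not all, of that dependence — as in the design the package follows.
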