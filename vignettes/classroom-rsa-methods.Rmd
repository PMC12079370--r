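---
title: "Methods: event-level inter-subject RSA for classroom fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-level inter-subject RSA for classroom fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(classrsa)
```

# The analysis problem

A teacher delivers a lecture to a group of students while every
participant's cortical hemodynamics are recorded with wearable fNIRS
(multichannel HbO time series at 10 Hz). The lecture is segmented into
*knowledge events* — minimal conceptual units with onsets and offsets — and
each event is summarized by a semantic *topic vector*. Two questions drive
the analyses in this package:

1. **Representation.** Do the students' brains carry the structure of the
   taught knowledge? Structure is defined as the event-by-event cosine
   similarity of topic vectors (the *knowledge matrix*), and its neural
   counterpart as an event-by-event *brain matrix* built from inter-subject
   correlations of event-locked signals.
2. **Construction and transmission.** Is that structure re-organized rather
   than copied (event-boundary contrast, leave-one-dyad-out decoding,
   inter-subject pattern correlation), and does the teacher's representation
   precede the students' (time-lagged teacher-student synchronization)?

Because classroom recordings of this kind are not publicly distributable,
the package pairs every analysis with a synthetic-cohort generator whose
ground truth is known, so each stage is validated by parameter recovery
rather than by reference to irreproducible data.

# The core statistics

## Knowledge matrix

For events $m, n$ with topic vectors $w_m, w_n \ge 0$,
$K_{mn} = \cos(w_m, w_n) = \frac{w_m^\top w_n}{\|w_m\| \, \|w_n\|}$.
The embedding itself is an input: the package consumes per-event vectors of
any dimension (a pretrained topic model is deliberately not shipped). The
*node degree* of an event is the mean similarity of its available edges,
used for network summaries.

## Brain matrix by inter-subject correlation

Within-subject correlations between two events of the same recording are
aliased by the slow autocorrelation of hemodynamics. The brain matrix is
therefore built *across* subjects: for participants $i, j$ and events
$m, n$,

$$B^{(ij)}_{mn} = \tfrac12\left[\,r(x_i^{(m)}, x_j^{(n)}) +
                                 r(x_j^{(m)}, x_i^{(n)})\,\right],$$

with $x_i^{(m)}$ the channel signal of subject $i$ during event $m$. The
average of the two directions makes $B^{(ij)}$ symmetric by construction.
Events differ in duration; the two series entering each correlation are
truncated to the shorter length, anchored at event onset (an alternative —
time-warping to a common length — introduces resampling artifacts and is
not used). Cells with fewer than 3 overlapping samples are masked. Each
subject's matrix is the average of its $N-1$ pair matrices. Per-channel
representational similarity is the Spearman correlation between the
strictly-lower triangles of the subject's brain matrix and the knowledge
matrix, restricted to the intersection of the two availability masks, and
averaged across subjects.

No hemodynamic shift is applied when event windows are extracted for RSA;
the delay compensation appears only in the boundary contrast where window
placement is the point. Both choices are configurable.

## Permutation inference

The observed cross-subject mean r is compared with a surrogate null: in
each iteration every subject's channel series is transformed and the whole
matrix pipeline re-run. Three surrogate families are provided:

* `phase_randomize` (default): random Fourier phases, amplitude spectrum
  (hence autocorrelation) preserved — the conservative choice for smooth
  hemodynamic signals;
* `time_shuffle`: random permutation of samples;
* `circular_shift`: random rotation, preserving everything but alignment.

The one-tailed p-value is $p = (1 + \#\{r_{null} \ge r\}) / (1 + n_{perm})$,
which can never be exactly 0. Channels (or grid cells) are corrected by
Benjamini–Hochberg FDR at $q < 0.05$. For circular shifts the engine draws
shifts without replacement whenever possible, so a request for all
$n - 1$ rotations reproduces the exhaustive null exactly — this is the
anchor for the oracle tests.

## Boundary contrast

Event segmentation in higher-order cortex shows up as transient responses
after event offsets. After shifting the signal forward by 6 s (hemodynamic
delay), the *boundary* pattern is the mean z-scored activity in the first
15 s after each offset and the *non-boundary* pattern the mean over the
middle 15 s of each event (6 s windows for short recalled events). Events
shorter than the window are dropped from the non-boundary average only;
boundary windows always exist post-offset, may slide into the next event
(boundaries are defined by the material, not the recording), and are
dropped when they overrun the phase end. The per-subject difference is
tested with a paired t-test, reported with Cohen's d and a 95% CI.

## Leave-one-dyad-out decoding and pISC

All $G = N(N-1)/2$ pair matrices form a population. Holding out one pair,
the training pairs' matrices are averaged and a univariate least-squares
regression (intercept + slope) maps mean brain similarity to knowledge
similarity over lower-triangle cells; applied to the held-out pair it
yields a predicted knowledge matrix. The model is univariate because a
single averaged brain matrix is the only regressor the design provides;
the intercept is included so the fit is affine-invariant. Each student's
$N-1$ predictions are averaged; Spearman similarity to a reference
structure (original, or actually-recalled, knowledge) is Fisher-z
transformed (inputs clipped at $|\rho| \le 1 - 10^{-7}$) and tested against
zero. Students contributing fewer than 3 jointly available cells — e.g.
fewer than 3 recalled events — are excluded.

Neural pISC is each student's mean Pearson correlation (lower triangles)
between their predicted matrix and everyone else's, Fisher-z transformed;
behavioral pISC is the mean Jaccard similarity of binary recall vectors,
with the similarity of two empty vectors defined as 0 (no shared recall
signal) and flagged. Brain-behavior coupling uses a partial Pearson
correlation controlling for covariates such as age and socioeconomic
status, one-tailed on $n - k - 2$ degrees of freedom.

## Time-lagged teacher-student synchronization

For every teacher channel x student channel pair and every lag on a
$\pm$6..14 s grid (2 s steps; positive lag = teacher precedes), the
teacher's series is shifted, the teacher's event matrix is built with the
same inter-subject machinery (teacher vs each student, averaged over
students), and correlated (Spearman, lower triangles) with the student
cohort's mean matrix at that channel. A teacher-autocorrelation variant
exists behind a flag but is non-default, since within-subject
autocorrelation is exactly what the inter-subject construction avoids.
Lags below 6 s are excluded by default (within the hemodynamic response
delay, lag separation is not interpretable); the grid is configurable.
Shifted event windows that leave the recorded span drop their events from
the matrix rather than being zero-padded. Permutation inference surrogates
the students' series and BH-FDR corrects across the whole grid.

# Preprocessing

Stages run in a fixed order, so that quality control sees only raw data:

1. **Artifact screening.** Non-overlapping 10 s windows per channel; samples
   beyond the window mean ± 3 SD are artifacts. A channel is bad above 5%
   flagged samples; a subject is excluded above 30% bad channels. The
   stride is configurable (the running-window convention differs between
   labs); non-overlapping windows are the default.
2. **Steady-state trimming.** 15 s off each end of every phase window;
   event onsets are re-referenced by the same amount.
3. **Artifact correction.** Linear interpolation across flagged samples.
   This is a deliberate, simple correction: the numeric contract of this
   stage is the flagging rule, and the interpolator is a replaceable hook.
4. **Global component removal.** Spatial PCA across the good channels of
   one participant; the leading components reaching 80% cumulative variance
   are projected out. Spatial decomposition across channels is the
   convention for global physiological noise (skin blood flow) in fNIRS.
5. **Band-pass.** 0.01–0.5 Hz, 3rd-order Butterworth applied
   forward-backward (zero phase — phase distortion would bias the lag
   analyses). Channels are demeaned first, which reduces filter edge
   transients to numerical noise.
6. **Z-scoring** per channel over the retained phase span. Whether to
   standardize per phase or per session is ambiguous in common practice;
   the default is per phase, configurable.

# The synthetic generator

`synth_config()` + `simulate_cohort()` produce cohorts with known truth:

* **Event sets.** Durations are 6 s + truncated-exponential, bounded by
  `duration_range`; under the default (6, 200) s range the scale is chosen
  so the mean is ≈ 52.7 s, matching long-tailed lecture segmentations.
  Events tile the session contiguously after a 20 s lead-in; the recording
  adds a ≥ 40 s tail (padded to a 5-smooth sample count so FFT surrogates
  stay $O(n \log n)$).
* **Topic vectors** from a symmetric Dirichlet (concentration 0.4 by
  default — sparse enough to spread cosine similarities over (0, 1)).
  K = 12 topics by default: the structure of the knowledge matrix, not the
  dimension of the embedding, is what the analyses consume.
* **Embedded signal.** K shared smooth basis waveforms (low-pass-filtered
  white noise, 0.2 Hz cutoff — inside the analysis band so the 0.01–0.5 Hz
  band-pass cannot destroy the structure), orthonormalized, with event
  $m$'s in-event time course mixing them by its unit-normalized topic
  weights. The embedded channel carries
  $\sqrt{\rho}\, s_m(t) + \sqrt{1-\rho}\,\varepsilon(t)$, making the
  expected inter-subject event-pair correlation track cosine similarity
  with overall scale $\rho$ (`embed_strength`). The magnitude of shared
  signal in real classroom data is unknown; $\rho$ is a free simulation
  parameter, not an estimate.
* **Noise.** AR(1) channel noise (coefficient 0.3) plus one per-subject
  global series (AR(1), 0.97) added to every channel with random gain in
  [0.5, 1.5] — so PCA removal is testable against the stored truth.
* **Boundary transients.** A 6 s neural burst convolved with the canonical
  double-gamma HRF (peak 6 s), peak-normalized, anchored at every event
  offset on the embedded channel; a `midpoint` variant anchors it mid-event
  to emulate a reversed boundary effect. An extended burst rather than a
  bare HRF impulse is used because a 15 s post-offset window is designed to
  capture an extended response; a lone impulse leaves nearly as much mass
  in mid-event windows of short events as in boundary windows, making the
  contrast's sign unstable across event sets.
* **Teacher.** The deterministic (embedded + boundary) structure is
  advanced by `teacher_lead` seconds (default 8 s), so the lag scan has a
  known recoverable peak.
* **Recall.** Per-event Bernoulli recall; recalled-event matrices use
  Dirichlet-resampled topic vectors, the simplest one-parameter divergence
  between recalled and original structure. The same resampling, applied
  per student to the embedding weights (`subject_distortion`), provides a
  controllable dial for between-student representational variance, which
  the pISC analyses require.
* **Artifacts.** Brief (0.2 s) alternating-sign spikes spread one per
  segment. Spikes are deliberately brief and spread out: the mean ± 3 SD
  window rule is self-masking for long dense excursions (they inflate the
  window SD), which is a property of the rule, not of the detector.

The generator does **not** emulate raw optical densities or the
Beer–Lambert conversion, deoxy-hemoglobin, head-motion kinematics, real
speech semantics, or systematic inter-subject latency differences beyond
the teacher lead. Passing recovery tests therefore show the analysis chain
is correct and well-calibrated under the assumed signal model — not that
real classroom data satisfy that model.

# Validation conditions and problem sizes

The test suite validates by parameter recovery under fixed seeds. Sizing
choices (the package's own):

* Monte-Carlo fixtures use event durations of (6, 40) s so that the
  permutation loops (hundreds of cohorts x 200 surrogate iterations x all
  pair matrices) remain tractable on one core; the event-duration floor of
  6 s and all cohort/event/permutation counts match the analysis contracts.
* Null-calibration cohorts set `boundary_amp = 0`: offset-locked transients
  are *deterministic structure shared across subjects*, not exchangeable
  noise, so they do not belong in a null condition for a surrogate test of
  the stochastic component.
* Boundary-recovery cohorts set `embed_strength = 0` for the complementary
  reason: the embedded event signal contributes deterministic per-event
  window means that act as event-set-level noise in the boundary contrast.
* The RSA-vs-rho monotonicity check re-uses the same seeds at every rho
  level (paired design), removing event-set variability from the
  comparison.
* The decoding null check pools 30 independent rho = 0 cohorts and tests
  the across-cohort mean against its across-cohort SE. Within one cohort
  the students' decoded similarities share the same pair matrices, so the
  within-cohort one-sample t is anticonservative by construction — a
  property of the leave-one-dyad-out design worth remembering when
  interpreting its p-values on real data.

# Numerical choices and edge cases

* Time is in seconds, sample indexing 0-based, event intervals half-open
  `[onset, offset)`; onsets are rounded to whole samples at generation.
* Spearman ties get average ranks; correlations over degenerate
  (zero-variance or < 3 sample) windows are masked, not propagated.
* Fisher z clips at $|\rho| \le 1 - 10^{-7}$; p-values are never 0 by the
  add-one permutation formula; BH q-values are monotone.
* Zero-variance channels are zeroed and flagged rather than producing NaNs;
  zero-variance decoding predictors skip their fold with a flag.
* One master seed fans out deterministically to per-stage child seeds
  (kept below $2^{31}$).

# Known limitations

* The leave-one-dyad-out decoder is not exactly unbiased under the null:
  because the held-out pair is excluded from the training mean, its own
  brain-knowledge covariance is slightly anti-correlated with the fitted
  slope, producing a small negative mean decoded similarity on cohorts
  with no embedded signal (of order z ≈ −0.03 at N = 20, M = 26, and
  present even for white noise). Combined with the shared-pair
  anticonservativeness above, null-calibration expectations for this
  decoder should be set by simulation, not by the nominal t distribution.
* Lag-scan antisymmetry (shifting the students instead of the teacher
  negating the peak) holds when event durations are long relative to the
  lag; for events comparable to the lag, shifting the measured party slides
  the correlation windows onto neighboring events and the reversed peak
  degrades.

* The 80% spatial-PCA rule is aggressive when channels are nearly
  independent (no dominant global component): it then removes many
  near-isotropic directions and can attenuate an embedded signal. With a
  realistic global component the first components absorb it and the
  embedded structure survives — the regime the rule is meant for.
* The truncated-window correlation makes even the noiseless brain matrix an
  imperfect rank-copy of the knowledge matrix (basis overlap over a
  truncated window is not exactly the cosine), so mean RSA r saturates
  below 1 at rho = 1.
* SNIRF containers are not read directly; recordings travel in a documented
  plain-text archive (TSV + JSON) or are constructed in code.
* Inference helpers assume one cohort per call; multi-lesson pooling is the
  caller's responsibility (run per lesson and combine).
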