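---
title: "Isolating visuomotor prediction errors in EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating visuomotor prediction errors in EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachpe)
```

## The scientific problem

When a reach is made under a visuomotor rotation, the visual consequences of
the movement differ from what the motor system predicted. This mismatch — the
visuomotor prediction error (PE) — is thought to drive implicit sensorimotor
adaptation, but it usually co-occurs with task errors (target misses), with
changed visual input, and with changed motor output, so its neural signature
is hard to isolate. The paradigm this package implements separates PE from
those confounds by comparing two conditions with matched kinematics, matched
visual input and no task errors:

* **STR** — the cursor is rotated 45° counterclockwise and the participant is
  instructed to counter it by "striking through" the neighbouring target 45°
  clockwise of the cued one. The movement succeeds, but the predicted and
  observed cursor directions disagree: a PE is present.
* **POST** — after ~100 consecutive rotated reaches the internal forward
  model has adapted; the same movement now produces the *expected* rotated
  feedback, so the PE is attenuated.

EEG contrasts between STR and POST (and between STR and unrotated NULL
reaches) then index PE processing. The pipeline reproduces the full chain:
task geometry and trial scheduling, reach kinematics with trial rejection,
EEG preprocessing, surface-Laplacian current source density (CSD),
Morlet-wavelet event-related spectral perturbations (ERSPs), ERP component
scoring, and binned nonparametric statistics with false-discovery-rate
control. A synthetic-data generator with known ground truth makes every
stage testable without access to human recordings.

## Task geometry and scheduling

The geometry (`task_geometry()`) places two targets 8 cm from a central
start circle at ±22.5° around the midline; angles are measured
counterclockwise from the rightward horizontal (monitor "up" = 90°), so the
left target sits at 112.5° and the right at 67.5°. The +45° cursor rotation
maps the ideal strategy aim (67.5°) exactly onto the cued left target — the
geometry closes by construction, and `cursor_position()` is an exact
rotation (|cursor| = |hand|).

`generate_schedule()` builds the 596-trial session: 96 STR, 152 NULL-right
and 152 NULL-left trials interleaved in the first 400 trials, followed by
196 uninterrupted rotated adaptation trials whose final 96 form POST. The
interleaving constraint — at least two NULL trials between any two STR
trials — is sampled *uniformly over all valid interleavings* rather than by
rejection: STR positions are drawn as an ordered sample from a gap-reduced
index set and re-inflated (a bijection onto the valid position sets), after
which left/right NULL labels are shuffled. Rejection sampling of whole
interleavings was rejected as a design: its acceptance probability at these
counts is astronomically small, while the bijection gives the same uniform
distribution in one pass and is deterministic under the seed.

## The synthetic reach model

`simulate_reaches()` generates 100 Hz minimum-jerk trajectories of ~300 ms
(sampled per trial), terminating 1–2 cm past the target ring and holding the
final position. Implicit adaptation follows a single-state model,

x[n+1] = retention · x[n] − learning_rate · e[n],

where `e[n]` is the *sensory* prediction error: the imposed rotation (45°)
on rotated trials and 0 on NULL trials (pure decay). A task-error definition
of `e` would predict no drift at all when the strategy succeeds, which
contradicts the drift-despite-hitting phenomenon the paradigm relies on; the
SPE reading is therefore used. The defaults (retention 0.98, learning rate
0.012, motor noise SD 2°) were fixed once from the implicit-adaptation
literature's constraint that ~100 consecutive rotated reaches produce about
25° of implicit compensation; they are not fitted to any outcome.

Two deliberate simplifications are documented here because they are visible
in simulated summaries:

* A single-state model cannot simultaneously produce large per-trial drift,
  near-zero absolute NULL-trial angles, and a 25° asymptote (that requires
  two timescales). With the chosen defaults the interleaved-phase state
  equilibrates near −4°, so absolute hand-vs-target angles carry a small
  constant offset that the real data do not show; the *contrast* (trials
  after vs before STR, clockwise shift) is unaffected and is what the
  statistics use.
* On uninterrupted adaptation trials the *expressed* aiming residual decays
  geometrically from the state at adaptation entry (`task_correction`),
  emulating the rebalancing of explicit strategy and implicit adaptation
  that keeps total compensation near 45°. Without it, every POST reach would
  miss by ~20° and be rejected by the target-hit rule, contradicting the
  matched kinematics the paradigm requires. The latent implicit state still
  follows the recursion above and is recorded as ground truth.

The generator does not attempt to reproduce the small STR-vs-POST difference
in final hand position reported for the human data; that feature is
explicitly non-emulated.

## Kinematic summaries and trial rejection

Movement onset is the first sample outside the 0.5 cm start circle;
termination is the first sample at or after the 8 cm crossing whose speed
falls to or below 1.5 pixel/s (pixel pitch configurable, default
0.035 cm/pixel — a typical CRT; the true pitch of the original display is
unrecoverable). Speeds use central differences without smoothing. The
hit test replaces unrecoverable pixel overlap with its continuous analogue:
the rotated cursor disc overlaps the target disc when their center distance
is at most the sum of the radii (1.0 cm).

The angle at peak velocity is defined as *target vector angle minus hand
vector angle*, so a clockwise hand deviation is positive and clockwise
drift appears as an increase — the convention under which the published
drift contrast (reaches after STR minus reaches before STR) is positive.

Rejection uses inclusive boundaries: RT or MT ≤ 150 ms or ≥ 600 ms, or a
target miss. The text these rules come from prints "≤150 ms or ≥600 ms",
so both ends are treated inclusively; `reject_trials()` is idempotent and
order-independent.

## EEG synthesis

`simulate_eeg()` builds a continuous 500 Hz recording with one
movement-onset event per trial (onset-to-onset spacing 5.5 s, matching the
task's pre-cue, reaction, movement and hold phases). The signal sums:

* **1/f background**: 12 pink-noise sources synthesized in the frequency
  domain and projected through smooth random scalp topographies (Gaussian
  profiles on the sphere, widths 30–70°), giving spatially correlated noise
  with an average channel SD of 10 µV, plus 1 µV sensor white noise;
* **line noise**: a common 60 Hz sinusoid with per-channel gain;
* **injected components**, each scaled per condition and projected with a
  Gaussian topography peaked over the right-parietal (P2/P4/PO4) or
  mid-frontal (Fz/FC1/FC2) ROI: a parietal negativity at ~170 ms and a
  mid-frontal negativity at ~220 ms (Gaussian envelopes, latency jitter SD
  10 ms); amplitude-modulated bursts at 3 Hz (0–500 ms, parietal), 6 Hz
  (80–440 ms, frontal) and 13 Hz (100–1000 ms, parietal) with half-cosine
  envelopes; and optional >150 µV blink-like transients on configured
  trials;
* **between-subject variability**: one Gaussian dB jitter per effect family
  per call (SD 0.75 dB).

Burst gains are expressed in dB relative to a base amplitude; the default
condition gains (e.g. +3 dB parietal low-theta in STR vs 0 dB elsewhere)
are tuning choices sized so that group effect sizes land in the moderate-
to-large range (Pearson r ≈ 0.4–0.6 at n = 15) reported for this paradigm —
they are not measured physiological values, and `null_effects()` removes
every condition dependence for false-positive checks. What passing tests on
these data show is that the *pipeline* recovers known injected structure at
realistic signal-to-noise; they cannot certify performance on real EEG,
which has richer artifact structure (eye movements, muscle, drifting
impedances) and less stationary backgrounds.

## Preprocessing

The stage order is fixed: zero-phase band-pass (1–100 Hz) and notch
(59–61 Hz) filtering → average reference → epoching (−2500 to +2500 ms
around movement onset, half-open grid: 2500 samples at 500 Hz, onset sample
on the post-onset side) → baseline correction (mean over [−500, 0) ms per
trial and channel) → kinematic-rejection intersection → amplitude screening
(strictly >150 µV) → component-based cleaning → CSD.

The filters are Butterworth (band-pass order 4, band-stop order 2; the
source text names only corner frequencies, so family and order are
documented assumptions). They are applied at zero phase by multiplying the
signal spectrum with the squared magnitude response — the transfer function
of forward-backward filtering — which preserves ERP latencies exactly;
equivalence with a time-domain forward-backward implementation is asserted
in the tests away from the recording edges.

Independent-component *decomposition* is out of scope (an established ICA
implementation is assumed); `score_components()` implements only the
rejection heuristic, quantifying three qualitative criteria: (1) spectral
slope of the log-log power spectrum over 2–40 Hz ≥ 0 (EEG power should fall
with frequency), (2) more than half of the topography's squared-weight
energy on electrodes beyond 65° polar angle (scalp-rim sources), and
(3) excess kurtosis above 5 (spurious bursts). A component is artifactual
when at least two flags are raised. All three thresholds are configurable,
documented defaults.

Whether amplitude screening preceded or followed ICA is ambiguous in the
source description; it is implemented pre-ICA, matching the stated order of
operations.

## Surface-Laplacian CSD

Scalp potentials are converted to current source density with spherical
splines: `G(i,j) = Σ (2n+1)/(n(n+1))^m P_n(cos θ_ij)/4π` and
`H(i,j) = Σ (2n+1)/(n(n+1))^(m−1) P_n(cos θ_ij)/(4π r²)`, with m = 4,
smoothing constant 10⁻⁵ added to G's diagonal, head radius 10 cm, and the
Legendre series truncated at 50 terms (the m = 4 series converges far below
10⁻¹⁰ by then; the truncation is configurable and the tests validate the
series against an independent Laplace-integral evaluation of P_n at 100
terms). The solve uses the constrained formulation — spline weights sum to
zero with a free constant — so the output is reference-free: adding any
constant across channels leaves the CSD unchanged. The transform is
precomputed as a channels × channels matrix and applied per sample; output
units are µV/cm².

Electrode positions are idealized template coordinates for the 64-channel
actiCAP layout (`acticap_montage()`): the outer 10% ring of the extended
10/20 system at 72° polar angle, midline electrodes on an 18° sagittal
grid, intermediate electrodes by great-circle interpolation. A reduced
32-channel option retains both analysis ROIs and is used for scaled
simulations. Per-subject digitizations are not modelled.

Whether ERSPs were computed on CSD or on potentials is implied rather than
stated by the source's ordering (CSD precedes time-frequency decomposition);
the pipeline computes them on CSD, and `wavelet_power()` accepts either.

## Time-frequency decomposition

Complex Morlet wavelets span 1–100 Hz in 1 Hz steps with cycle counts
rising linearly 3 → 12.9 in 0.1 steps (σ_t = cycles/2πf), unit-energy
normalized, truncated at ±3σ. Convolution is performed in the spectral
domain (asserted equivalent to direct convolution), and power is the
squared magnitude. Any output sample closer to an epoch edge than a
wavelet's half support is marked invalid (`NA`) rather than padded or
reflected — the ±2500 ms epoch exists precisely to buffer the analysis
window (−500 to +1000 ms), and at 2 Hz and above the buffer absorbs the
full support.

Per condition, single-trial power is aggregated with the *median* across
trials (robust to outlier trials), the baseline power is the time-mean of
the median power over [−500, 0) ms, and the time-course is expressed as
`dB = 10·log10(RP/BP)`. Baseline normalization is strictly per condition,
so slow drifts in baseline power cannot masquerade as condition effects.

## ERP scoring and ROIs

CSD time-courses are pooled (plain mean) over the right-parietal ROI
(P2, P4, PO4) and the mid-frontal ROI (Fz, FC1, FC2). The visual N1 is the
window minimum in 125–200 ms minus the mean over 0–50 ms (peak-to-baseline;
no P1 reference is assumed because one cannot be identified reliably), and
the FRN is the window minimum minus the window maximum within 200–600 ms —
reported as min − max, hence always ≤ 0, so that a *greater* FRN is *more
negative*, matching the sign of published values. Peaks are global window
extrema rather than local extrema, which is robust on noisy averages.
Scoring windows are closed on the sample grid, and both scores are computed
on per-subject condition averages (the group statistic's unit), not on
single trials.

## Statistics

Time-courses are averaged into contiguous half-open 20 ms bins: 15 bins for
the CSD window (100–400 ms) and 50 for the ERSP window (0–1000 ms). Each
bin is tested across subjects with a paired Wilcoxon signed-rank test in
the convention that reproduces every published (W, z) pair exactly: zero
differences dropped, average ranks for ties, W = sum of ranks of positive
differences, z = (W − n(n+1)/4)/√(n(n+1)(2n+1)/24) with *no* continuity and
*no* tie-variance correction, two-tailed normal p, and effect size
r = |z|/√(2n). The numeric agreement (W = 119 → z = 3.35, W = 60 → z = 0,
W = 102 → z = 2.4; r = 0.61/0/0.44) is the evidence for this convention;
how the original analysis handled ties cannot be proven uniquely from it.

Multiple comparisons across the k bins are controlled with the
Benjamini–Hochberg procedure in its explicit step-up form: p values ranked
in decreasing order, thresholds FDRα(n) = α(k+1−n)/k, and the highest-
ranked p at or below its threshold is significant together with all
smaller p values. The tests cross-check the acceptance set against
`p.adjust(method = "BH")` on 1000 random vectors. Scalp z-maps apply the
same signed-rank z per electrode to window-averaged values over each
significant window.

Band selection for ERSP contrasts is automated as a stated surrogate for
selection by visual inspection: contiguous frequency runs whose mean |dB|
over the post-onset window exceeds a quantile (default 0.75) of the
per-frequency scores, computed on the *condition-averaged* spectrogram so
the selection is orthogonal to the ensuing contrast, with the configured
bands (parietal 2–4 and 8–18 Hz; frontal 5–7 and 10–35 Hz) as the fallback
and as the defaults used by `run_analysis()`.

## Problem sizes, tolerances, and numerical choices

* `run_analysis()` defaults describe the full study (15 subjects, 596
  trials, 64 channels). The packaged tests and the acceptance script run
  the *scaled setting*: 15 subjects × 40 trials per contrasted condition,
  32-channel montage, parietal 2–4 Hz band — chosen so a complete
  simulation study runs in minutes while keeping the group-level statistics
  at the study's n. Monte-Carlo sizes are 6 simulations for the detection
  rate (threshold ≥ 90%), 5 for the zero-gain null (mean false-discovery
  proportion ≤ 0.05 + 2 MC SE), and one run for N1 depth recovery
  (tolerance 35% of the injected depth, set a priori for a window-minimum
  statistic at this noise level and trial count).
* Scaled schedules keep the real design's STR density (40 STR : 126 NULL ≈
  24%); packing STR trials at the minimal gap would leave no washout
  between them and abolish the drift contrast.
* Wavelet kernels are truncated at ±3σ (amplitude ~1% of peak); edge
  validity uses the same support. The dB identity is exact to numerical
  precision and asserted at 10⁻¹².
* The spline solve adds λ = 10⁻⁵ only to G's diagonal; degenerate montages
  (coincident electrodes, singular systems) fail loudly rather than
  silently regularizing further.
* Degenerate Wilcoxon bins (all differences zero) carry p = 1 into the FDR
  step rather than NA, so an identical-condition contrast reports "no
  significant bins" instead of failing.

## Known limitations

* The adaptation generator is single-state (see above); absolute NULL/STR
  angles carry a small constant offset not present in real data.
* Idealized template electrode positions stand in for per-subject
  digitization; CSD magnitudes on real caps will differ in detail.
* The ICA decomposition itself, ocular regression and bad-channel
  interpolation are out of scope; only the component-rejection heuristic is
  provided.
* Synthetic effect amplitudes are calibration choices, so simulated power
  values are not comparable to published µV/cm² or dB magnitudes — only the
  statistical behaviour (detection, false-positive control, sign and
  localization of effects) is.
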