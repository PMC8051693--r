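---
title: "Models and methods behind hypnodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hypnodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnodyn)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices made where the underlying methodology
leaves room, and what the synthetic-data generator does and does not
emulate.

## The Markov model of state dynamics

Vigilance states scored in fixed 5-s epochs are treated as a first-order
(memoryless) Markov chain over wake, NREM and REM sleep: the probability
of the next epoch's state depends only on the current state. The
transition probability is estimated as a conditional probability — the
number of times state $Y$ is followed by state $X$ in the next epoch,
divided by the number of successor-bearing $Y$ epochs — and the marginal
state probability as the label frequency over all scored epochs.

The **fragmentation index** of a state is
$\mathrm{FI}(X) = 1 - p(X \mid X)$. It is 0 when every observed successor
of $X$ is again $X$ (perfect consolidation) and 1 only when the state is
completely fragmented. Two deliberate edge rules:

* A state observed without any successor (or not at all) has an
  *undefined* FI, returned as `NA` rather than 0. Severe REM suppression
  is the practical case: a number would be an artifact of scarcity, not a
  measurement.
* Artifact epochs break transition pairs rather than splicing their
  neighbors together: the pair spanning an artifact is simply not
  counted. Splicing would manufacture transitions that never happened.

Two estimators are provided for multi-session data. For paired group
statistics, each subject contributes their own probability matrix and the
test runs across subjects (`transition_matrix()` per session +
`compare_conditions()`); this matches testing "probability vector values"
within subject. For recovering a single shared generating matrix,
`pool_transitions()` sums raw counts across sessions first — the
efficient pooled estimator, which weights each session by its occupancy.

Hourly analyses (`hourly_fi()`, binned `state_times()` and
`count_transitions()`) give each 1-h block its own transition matrix;
transitions across block boundaries belong to neither block, and a binned
transition is assigned to the bin of its *destination* epoch ("transitions
into wake during hour $k$").

Latencies to NREM or REM onset are times to the first epoch of the state;
when the state never occurs the latency is censored at the recording
duration (21,600 s for 6-h sessions) and flagged, which is exactly the
form Kaplan-Meier estimation and the log-rank test need
(`km_logrank()`). The survival comparison method is the package's choice
of the standard two-sample log-rank test.

## Spectral estimation

All EEG measures run on *artifact-free, non-transition* 5-s epochs.
"Non-transition" is defined here as: the epoch's state equals that of
both neighbors (edge epochs are compared to their single neighbor). This
is the strictest common reading; it discards every epoch adjacent to a
state change, so no window mixes the electrographic signatures of two
states.

`multitaper_psd()` averages eigenspectra over $K = 3$ discrete prolate
spheroidal (Slepian) tapers with time-bandwidth product $NW = 2$ on 5-s
windows, giving a 0.2 Hz frequency grid and a spectral concentration
half-width of 0.4 Hz. The tapers are computed from the classical
symmetric tridiagonal formulation, with the top eigenvalues located by
Sturm-sequence bisection and eigenvectors by shifted tridiagonal inverse
iteration (the start vector is chosen outside the symmetric/antisymmetric
symmetry classes, and iterates are re-orthogonalized against
previously-found tapers). Results are cached per window length. The
estimator satisfies Parseval to within sampling error, which the test
suite checks against the window variance.

Band powers integrate the PSD over seven bands — slow oscillations
0.5–1 Hz, delta 1–4, theta 4–9, sigma 9–15, beta 15–30, low gamma 30–45,
high gamma 75–115 — and are normalized by the summed power over the
bands, so shares sum to 1 and are invariant to signal gain. The
45–75 Hz range is excluded from *every* analysis (band shares, coherence
summaries, and the complexity filter alike): it is a guard band around
mains interference and the notch filters applied to some recordings.
Integrated power (rather than mean density) is used because the
normalizer is "the sum of the power in all bands"; shares differ from the
mean-density convention only by bandwidth weighting.

Coherence uses the same tapers: auto- and cross-spectra are averaged
over tapers and windows, and the magnitude coherence
$C = |S_{xy}| / \sqrt{S_{xx} S_{yy}}$ is transformed with Fisher's
$z = \operatorname{atanh}(C)$, clipping $C$ at $1 - 10^{-6}$ so identical
channels stay finite. The z-transform is applied to the window-averaged
coherence (not per window); at least two windows are required, since a
single-window coherence estimate is identically 1.

## Normalized symbolic transfer entropy

Directed frontal–occipital connectivity is measured per frequency band.
Channels are band-pass filtered (zero-phase order-4 Butterworth, the same
filter for every band-limited step in the package), segmented into the
retained 5-s windows, and symbolized by ordinal patterns: with embedding
dimension $d_E = 3$ and band-matched delay $\tau$ (64, 28, 17, 9, 6, 2
samples at 512 Hz for delta through high gamma — each $\tau$ spans
roughly a quarter to half a period of its band), each time point maps to
the rank permutation of $(x_t, x_{t+\tau}, x_{t+2\tau})$. Ties rank by
temporal order, making symbolization deterministic and invariant under
strictly monotone amplitude transforms — NSTE therefore inherits
invariance to channel gain and offset.

For source $X$ and target $Y$ at transfer time $\delta$,

$$\mathrm{TE}(X \to Y; \delta) = H(Y_{t+\delta} \mid Y_t) -
H(Y_{t+\delta} \mid Y_t, X_t)$$

with plug-in entropies from the joint symbol frequencies *within the
window* (no pooling across windows). The normalized measure is

$$\mathrm{NSTE} = \frac{\mathrm{TE} - \overline{\mathrm{TE}}_{\mathrm{shuffled}}}
{H(Y_{t+\delta} \mid Y_t)}$$

clipped to $[0, 1]$, where the bias term averages 20 full random
permutations of the source symbol series (destroying directed coupling
while preserving the source's symbol distribution). This is the standard
construction in the symbolic transfer entropy lineage; the exact formula
is this package's documented choice. The transfer time is searched over
$\delta = 1$–50 samples (≈2–100 ms at 512 Hz) independently for each
direction and window, maximizing the *normalized* value, read literally
from "the transfer time that generated maximum NSTE". "Feedback" denotes
frontal→occipital, "feedforward" occipital→frontal. Windows with a
constant channel have undefined entropies and are reported missing; a
window with fewer joint samples than $d_E!^2$ carries a small-sample
flag.

## Surrogate-corrected Lempel-Ziv complexity

Per channel, the pipeline is: local-linear detrend → low-pass 115 Hz with
a 45–75 Hz band-stop (order-4 zero-phase Butterworth) → Hilbert
instantaneous amplitude → per 5-s window: binarize at the window mean →
LZ76 parse → normalize by surrogates. The ordering (detrend and filter
before surrogate generation, Hilbert after) is the package's documented
choice; the methodology fixes the steps but not their exact order.

Numerical specifics:

* **Detrend**: ordinary least-squares lines in 1-s windows advancing by
  0.5 s, predictions averaged where windows overlap. The window is chosen
  well below the epoch length (so state-scale structure survives) and
  well above the high-gamma period (so no analyzed rhythm is removed).
* **Binarization tie rule**: amplitude exactly equal to the window mean
  maps to 0 — deterministic, and measure-zero for recorded signals.
* **LZ76 variant**: exhaustive-history parsing; a final incomplete word
  counts as a word. This matches the canonical worked parse
  (`0001101001000101` → 6 words), and the implementation (C++, for the
  50-surrogates-per-window load) is checked in the tests against an
  independent naive reproduce-or-extend parser on *all* binary strings
  up to length 12.
* **Surrogates**: each of the 50 surrogates redraws uniform phases on the
  window's FFT (conjugate-symmetric, so the surrogate is real), keeping
  the magnitude spectrum — then re-runs the amplitude→binarize→parse
  chain. The corrected value raw/surrogate-mean is therefore ≈1 when the
  signal carries no structure beyond its linear spectrum (white noise
  lands within 0.05 of 1), and the correction, like the symbolization, is
  invariant to amplitude scaling. A constant window has no defined
  correction and is reported missing.

## The synthetic-data generator

`simulate_hypnogram()` draws state sequences from explicit transition
matrices. The built-in defaults (`default_transition_matrix()`) are
published group means from a chemogenetic-stimulation experiment in mice
(treatment) and vehicle controls — e.g. remaining-in-NREM 0.9384 vs
0.9621, NREM→wake 0.060 vs 0.031, NREM→REM 0.0017 vs 0.0072, and a
structural zero for wake→REM — with each row renormalized to sum exactly
to 1, since printed means do not. One oddity is carried verbatim: the
source reports the same control-arm value (0.9621) for remaining in NREM
and remaining in REM, possibly a transcription duplicate. Sessions
default to 4320 epochs of 5 s (6 h). `make_cohort()` derives per-subject
seeds from one master seed; optional between-subject jitter perturbs each
subject's matrix with Gaussian noise (clipped at 0, structural zeros
preserved, rows renormalized) but defaults to 0 so the arm matrices are
used verbatim.

`synthesize_eeg()` renders each bout with its state's generators:
band-limited oscillators (slow oscillations, delta and sigma spindles in
NREM; regular theta in REM; weak theta/low-gamma over strong broadband
noise in wake), $1/f^\alpha$ background noise, and an EMG tone channel.
Oscillator phases are randomized *per bout*, not per epoch, so no
artificial 5-s periodicity enters the spectra. Directed coupling is
delayed linear mixing — the occipital channel receives
$\mathrm{gain} \times$ the frontal signal delayed by a known lag
(defaults: 0.8 and 20 ms) — which gives an analytically known direction
and band for connectivity-recovery tests.

What the generator deliberately does **not** emulate: biophysically
realistic EEG (no cortical column dynamics, no spindle waxing/waning or
K-complexes), circadian or homeostatic drift across the session, mains
interference, and real artifact morphology (artifact epochs are rendered
as high-variance noise). Passing recovery tests on this generator
demonstrates that the estimators measure what they claim under known
ground truth — not that real mouse EEG satisfies the generator's
assumptions.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the
caller's RNG state. The test suite exercises the study-scale
configurations where the claim depends on them — transition-matrix
recovery pools 11 sessions of 4320 epochs; NSTE direction recovery uses
100 independent 5-s windows at 512 Hz with a 20-ms, gain-0.8 coupling;
white-noise complexity uses the full 50 surrogates — and smaller
configurations elsewhere: null calibration of the paired tests runs 500
replicate 11-subject cohorts of 1-h sessions (the size of a test does not
depend on chain length, so shorter null sessions trade nothing but
runtime), and per-state EEG summaries in tests use minutes-long sessions
at 256 Hz, which keeps full-pipeline checks fast while leaving every
parameter that affects the estimators at its default.

## Known limitations

* Hypnograms are single-session; light/dark phase splitting and
  multi-day designs are out of scope.
* EDF input is not supported; signals enter as CSV/text or in-memory
  vectors with an explicit sampling rate.
* The treatment-arm REM row of the default matrices generates so little
  REM sleep (the point of the treatment) that no estimator can pin its
  probabilities tightly at realistic session counts; analyses of REM
  under treatment are reported missing rather than extrapolated, and
  recovery guarantees are stated for the control matrix.
* Repeated-measures ANOVA with post-hoc families is intentionally not
  implemented; the pipeline emits tidy per-subject tables ready for
  external ANOVA tooling.
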