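---
title: "Methods: ripple detection, slow-gamma power, and theta-gamma coupling"
author: "ripplepac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple detection, slow-gamma power, and theta-gamma coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ripplepac)
```

## What the package computes

`ripplepac` analyzes single-channel hippocampal local field potential
(LFP) recordings, typically sampled at 1 kHz, during periods of extended
immobility. Three quantities are at its core:

1. **Sharp-wave ripples (SWRs)** — transient 150–250 Hz oscillations.
   The trace is band-pass filtered to the ripple band, the Hilbert
   envelope is computed, and events are the periods where the envelope
   exceeds its mean by 5 standard deviations for at least 15 ms, each
   extended to the surrounding crossings of the envelope mean. Durations,
   a median with bootstrap CI, and the incidence rate (events per second
   of immobility) summarize them.
2. **Slow-gamma power during SWRs** — a multitaper spectrogram is
   computed in a ±400 ms window around each SWR onset, averaged over
   events, z-scored per frequency row, and the z power is averaged over
   30–50 Hz and 1–100 ms after onset.
3. **Theta–slow-gamma phase–amplitude coupling (PAC)** — instantaneous
   theta (4–12 Hz) phase and slow-gamma (30–50 Hz) amplitude are taken
   from Hilbert transforms; amplitudes are binned by concurrent phase
   into $N = 18$ bins, normalized to a distribution $p$, and summarized
   by the modulation index
   $$\mathrm{MI} = \frac{\log N - H(p)}{\log N}, \qquad
     H(p) = -\sum_{j=1}^{N} p_j \log p_j,$$
   the Kullback–Leibler divergence of $p$ from uniform scaled to
   $[0, 1]$. $\mathrm{MI} = 0$ iff $p$ is uniform and $\mathrm{MI} = 1$
   iff all amplitude mass falls in one bin. Empty bins contribute via
   the convention $0 \log 0 = 0$.

A synthetic-LFP generator with exact ground truth closes the loop: every
stage is validated against signals whose event times, coupling strength
and spectral content are known by construction.

## Signal-processing choices

**Filtering.** Band-pass filters are Hamming-windowed-sinc FIRs applied
forward–backward (`signal::filtfilt`), giving exactly zero phase shift —
essential when event boundaries and phase estimates are read off the
filtered trace. The order spans roughly three cycles of the band's low
edge (e.g. 20 taps for 150–250 Hz at 1 kHz, 750 taps for 4–12 Hz); the
squared (two-pass) magnitude response leaves less than 1% ripple in the
passband and far more than 20 dB rejection one octave outside the band.
An order-4 Butterworth applied forward–backward is available via
`family = "butter"`.

**Edge handling.** One filter length at each end of the trace is treated
as transient-contaminated: those samples are excluded from envelope
statistics, event detection, and PAC. Events whose extent touches the
transient region or leaves the immobility mask are discarded (not
truncated) and counted in `n_discarded`, so duration statistics are never
silently censored.

**Analytic signal.** The Hilbert analytic signal is built by the FFT
half-spectrum method (negative frequencies zeroed, positive doubled).
The phase convention is `phase(cos(2*pi*f*t)) = 0`, so a sine sits at
$-\pi/2$ at its positive-going zero crossing. Phase is reported wrapped
to $(-\pi, \pi]$.

**Multitaper spectrograms.** DPSS (Slepian) tapers are computed from the
standard symmetric tridiagonal eigenproblem. Defaults are a 100 ms
window, 10 ms step, time–bandwidth NW = 3 and K = 5 tapers: a 100 ms
window resolves the 30–50 Hz band (10 Hz bins) while K = 5 averaged
eigenspectra cut estimator variance several-fold relative to a single
taper. These are recorded in every spectrogram's `taper_params`, since
no single convention exists.

**Z-scoring.** By default the per-frequency normalization statistics are
the mean and SD of that frequency's row of the event-averaged ±400 ms
matrix (`norm = "event_window"`), making each row exactly zero-mean,
unit-SD under its own recorded `norm_stats`; `norm = "session"` instead
normalizes by the whole recording's spectrogram, for sensitivity
analyses. Both the choice and the statistics are stored in the result.

## Detection details worth knowing

* Envelope mean and SD are computed over immobility samples only, with
  no iterative event-exclusion; one round of event-excluded
  re-estimation is available as `reestimate = TRUE` for sensitivity
  analysis.
* Event extension to the envelope-mean crossing is the full-event
  definition; cores whose extensions meet share one baseline-crossing
  run and merge into a single event whose peak is the envelope maximum
  of the merged span.
* Because extension runs backward until the envelope dips below its
  mean, detected onsets systematically *lead* the underlying burst start
  whenever pre-burst noise happens to sit above the mean — in synthetic
  tests the median onset error is within a few ms but single events can
  lead by a few tens of ms. This is a property of the event definition,
  not a bug, and should be remembered when aligning events to external
  clocks.
* The Hilbert envelope of a very short burst is wider than the burst:
  a 10 ms, 1.8-cycle ripple burst has an envelope spread of roughly
  14 ms by time–bandwidth necessity. The 15 ms minimum-duration rule
  therefore rejects 10 ms bursts reliably when they are moderately
  supra-threshold (tested at 3.5 SD peak amplitude), but extremely large
  bursts (8 SD and above) can smear past the criterion. Detection tests
  and the duration-contract checks use 3.5 SD bursts for this reason.

## PAC details worth knowing

* Phase bins start at $-\pi$ and are half-open on the right (the last
  bin closes at $\pi$). The bin count (default 18) is recorded in the
  result; MI varies smoothly but not negligibly with it, so comparisons
  should hold $N$ fixed.
* MI is invariant to any positive rescaling of the amplitude channel.
* The comodulogram evaluates MI on a grid of (phase, amplitude) band
  centers. The amplitude bandwidth (default 30 Hz) must comfortably
  exceed twice the highest phase frequency: the amplitude modulation of
  a carrier at $f_a$ coupled to phase $f_p$ lives in side-bands at
  $f_a \pm f_p$, and if those side-bands sit at the band edge the
  correctly-centred band is attenuated while an off-centre band that
  captures a carrier–side-band *beat* can outscore it, displacing the
  argmax. With a 4–12 Hz phase grid this mandates ≥ 24 Hz plus filter
  transition margin.
* An optional surrogate test (`n_surrogates`) circularly time-shifts the
  amplitude series and reports a z-score of the observed MI against the
  surrogate distribution. Caveat: for *strictly periodic* coupling (as
  in the deterministic generator), a time shift merely rotates the
  preferred phase and preserves MI, so the surrogate z cannot separate
  coupled from uncoupled periodic signals; it is informative for
  stochastic data only.
* PAC is computed over the immobility mask when one is supplied,
  otherwise over the whole edge-trimmed recording; MI per epoch of a
  chosen length is available by masking.

## The synthetic generator

The generated trace is
`noise + theta + gamma + ripple bursts`, with

* **noise**: pink (spectrally shaped $1/f$ power; log–log PSD slope −1)
  or white, SD 30 µV by default — the dominant broadband background of
  an LFP;
* **theta**: an 8 Hz, 60 µV cosine, whose exact phase is stored
  per-sample as ground truth;
* **gamma**: a 40 Hz carrier with envelope
  $A_\gamma [1 + k \cos(\theta(t) - \phi_0)]$, base amplitude 20 µV;
  $k \in [0, 1]$ is the programmed coupling strength and $\phi_0$ the
  preferred phase. The carrier is a constant-frequency tone so the
  phase-binned amplitude distribution, and hence MI, has a closed form
  to test against;
* **ripples**: Hann-windowed pure tone bursts at 180 Hz whose peak
  amplitude is 8 background SDs by default and whose durations are
  log-normal (median 50 ms, σ = 0.25 log-units) — onset, offset,
  amplitude and count are exact ground truth. Optionally each ripple
  carries a co-injected 40 Hz burst over its first 100 ms, emulating
  transient slow-gamma engagement during SWRs.

Ripple onsets form a renewal process confined to immobility epochs: a
hard 200 ms refractory gap (forbidding overlap, which would blur ground
truth) plus an exponential excess gap whose mean keeps the programmed
onset rate exact. A thinned Poisson process with the same refractory
would under-produce events by ~10% at 0.5 Hz, which would defeat
rate-recovery testing; the renewal construction avoids that bias by
design. All randomness derives from the mandatory integer seed, so a
config regenerates bit-identically.

What the generator does **not** emulate: the low-frequency sharp-wave
deflection that accompanies real ripples, movement and chewing
artifacts, non-stationary theta frequency drift, broadband gamma
(the carrier is tonal), and inter-channel structure. Tests passing on
this generator therefore establish the *algorithmic* correctness of
each stage under controlled conditions — they do not certify performance
on artifact-laden in-vivo data.

The three group profiles (`WT-like`, `AD-TMAS-like`, `AD-like`) are
preset configurations strictly ordered on ripple rate (0.30 / 0.20 /
0.10 Hz), ripple duration (median 60 / 45 / 32 ms), coupling $k$
(0.75 / 0.50 / 0.25) and ripple-locked gamma amplitude (12 / 8 / 4 µV),
with ~8% per-subject multiplicative jitter; they emulate the *direction*
of group differences in hippocampal pathology-and-treatment studies, not
any particular effect size.

## Statistics layer

Per metric, `group_report()` summarizes groups as mean ± SEM and routes
the omnibus comparison: one-way ANOVA with Scheffé post-hoc pairs when a
mean-centered Levene test and per-group Shapiro–Wilk checks both pass at
α = 0.05, otherwise Kruskal–Wallis with Bonferroni-corrected pairwise
rank tests. The route and both check p-values are always recorded and
can be overridden. The Scheffé pairwise statistic
$S^2 = (\bar x_i - \bar x_j)^2 / [\mathrm{MSE}(1/n_i + 1/n_j)]$ is
referred to $(k-1) F_{k-1,\,N-k}$ — implemented from the definition, as
it is rarely packaged — and is by construction never less conservative
than an unadjusted pooled t test. The unit of analysis (animal, epoch,
event) is whatever rows the caller supplies, and is deliberately not
imposed by the report layer.

## Numerical conventions

* Time is in seconds from recording start; intervals are half-open
  `[start, end)`; sample *i* covers `[(i-1)/fs, i/fs)`.
* The duration-CI bootstrap (default 10,000 resamples) takes a mandatory
  seed (default 0) so confidence intervals are bit-reproducible.
* Degenerate inputs are explicit: an all-zero trace yields zero events
  (not an error); a constant non-zero trace is a degenerate-input error;
  a constant trace's phase is undefined and flagged.
* Test problem sizes were chosen to make each property decisive yet
  quick: 8–10 s traces for detector/oracle equivalence (50 random
  configurations), 200–600 s per run for rate recovery (20 seeded runs
  per rate), 120 s for PAC oracles and comodulograms, 240 s × 21
  subjects for the cohort ordering, and 2000 null simulations for test
  size calibration.

## Known limitations

* Only single-channel analysis; no sharp-wave (stratum radiatum)
  component detection, no spike coupling, no streaming mode.
* Immobility is an input mask, not a computed behavioral state.
* The MI estimator is the entropy-normalized phase-binned index; the
  mean-vector-length and GLM families are out of scope.
* Event-boundary extension makes onsets noise-dependent (see above);
  durations are accordingly upper-biased relative to the injected burst
  core, uniformly across groups.
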