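# ripplepac

Hippocampal LFP analysis in R: sharp-wave-ripple detection, ripple-locked
slow-gamma power, and theta–gamma phase–amplitude coupling — with a
ground-truth synthetic LFP generator and the group-comparison statistics
that studies of hippocampal memory function typically report.

## The problem

Sharp-wave ripples (SWRs; transient 150–250 Hz oscillations during
immobility), slow gamma (30–50 Hz) engagement during ripples, and
theta-phase modulation of slow-gamma amplitude are standard
electrophysiological readouts of hippocampal memory circuits — all three
are altered in disease models and by neuromodulation. `ripplepac`
implements this analysis chain as a reusable, tested pipeline for anyone
with a single-channel LFP trace (CSV or float32 binary plus a JSON
sidecar) and an immobility interval table.

## The methods at its core

**SWR detection.** With ripple-band envelope $e(t)$ (Hilbert transform of
the 150–250 Hz zero-phase-filtered trace), events are maximal periods
where $e(t) > \mu_e + 5\sigma_e$ for ≥ 15 ms, each extended to the
nearest crossings of the envelope mean $\mu_e$; statistics are computed
over immobility samples only, and incidence is events per second of
immobility.

**Ripple-locked slow gamma.** DPSS multitaper spectrograms (100 ms
window, 10 ms step, NW = 3, K = 5) in a ±400 ms window around each SWR
onset are averaged over events and z-scored per frequency row; the
slow-gamma score is the mean z over 30–50 Hz and 1–100 ms after onset.

**Phase–amplitude coupling.** Theta (4–12 Hz) phase and slow-gamma
(30–50 Hz) amplitude from Hilbert transforms; amplitudes binned into
N = 18 phase bins and normalized to a distribution $p$; the modulation
index is the entropy-normalized KL divergence from uniform,

$$\mathrm{MI} = \frac{\log N - H(p)}{\log N} \in [0, 1].$$

A comodulogram evaluates MI over grids of phase and amplitude band
centers. Group comparisons run Levene's test, then one-way ANOVA with
Scheffé post-hoc or Kruskal–Wallis with Bonferroni-corrected pairs,
routed by variance/normality checks.

Everything is validated against a synthetic generator (pink noise +
theta + theta-coupled gamma + Hann-windowed ripple bursts at a
programmed rate) whose ground truth — event times, coupling strength,
theta phase — is exact. See the methods vignette
(`vignettes/ripplepac-methods.Rmd`) for every modeling and numerical
choice.

## Worked example

```r
library(ripplepac)

sim <- generate_lfp(synth_config(duration_s = 120, seed = 42,
                                 ripple_rate = 0.25, gamma_coupling_k = 0.7,
                                 ripple_gamma_amp = 10))
det <- detect_swr(sim$recording, sim$truth$immobility_mask)
det
#> <swr_result> 31 events over 120.0 s immobility (0.258 Hz); threshold 5 SD, min 15 ms; 0 discarded at boundaries

duration_stats(det, seed = 0)
#> <swr_duration_stats> n=31, median 56.0 ms (95% CI 54.0-64.0)

zs <- swr_triggered_spectrogram(sim$recording, det)
slow_gamma_power(zs)
#> [1] 0.5721  (z units; 30-50 Hz, 1-100 ms after SWR onset)

pac_mi(sim$recording, mask = sim$truth$immobility_mask)
#> <pac_result> MI = 0.0092 (phase 4-12 Hz, amp 30-50 Hz, 18 bins, 118500 samples)
```

The detector recovered a realized incidence of 0.258 Hz against a
programmed 0.25 Hz rate; median event duration (56 ms, bootstrap 95% CI
54–64 ms) reflects the generator's log-normal burst durations plus
baseline extension; the positive slow-gamma z score reflects the 40 Hz
bursts co-injected after each ripple onset; and MI ≈ 0.009 is the
coupling strength k = 0.7 as seen through 30–50 Hz-band noise dilution.
Results are tibble-friendly: `tidy()` gives event tables /
phase-bin distributions, `glance()` one-row summaries, and `autoplot()`
renders spectrograms, comodulograms and phase–amplitude distributions.

Full cohort runs (simulate or load recordings → detect → spectrogram →
PAC → group report, with provenance manifest) go through
`run_pipeline(run_config(...))`; a thin command-line wrapper is
installed at `inst/scripts/ripplepac`.

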