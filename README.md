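# optotheta

Electrophysiology analysis for optogenetic septo-hippocampal experiments:
multichannel LFP and sorted spike trains recorded while a light pulse
silences a septal cell population for 5 s every 20 s (15 s off – 5 s on,
10-minute sessions).  The package quantifies how that manipulation reshapes
hippocampal rhythms and septo-hippocampal coordination, and ships a seeded
synthetic-session generator so every estimator can be validated against
injected ground truth.

It is written for systems neuroscientists who have raw LFP (int16 binary +
JSON sidecar), sorted spike times (CSV) and a stimulation protocol (CSV),
and want the full analysis chain as tested, scriptable R functions.

## What it computes

- **Sharp-wave ripple detection.** 500 Hz → band-pass 100–250 Hz
  (zero-phase FIR) → rectify → 20 Hz Butterworth envelope → whole-trace
  z-score; events exceed 3.5 SD, extend to the 1 SD crossings, and merge
  within a 50 ms refractory window.  Per-event frequency/amplitude metrics
  come from 7-cycle Morlet wavelets; peri-stimulus density contrasts
  `(on − off)/off`.
- **Multitaper spectra** with in-package Slepian tapers (TW = 3, K = 5,
  half-bandwidth TW/T = 0.6 Hz on 5 s windows), Parseval-scaled densities,
  1/f whitening, normalised spike-train spectra, and per-band paired on/off
  tables (KS normality → paired t or Wilcoxon signed-rank, Benjamini–
  Hochberg FDR across bands: slow 0.5–3, theta 4–7, slow-gamma 20–40,
  high-gamma 60–140 Hz).
- **Event-triggered unit classification.** The sliding-sweeps template
  (±15 s, 500 ms bins, per-trial normalisation) is tested against a null
  built by permuting inter-spike and inter-onset intervals; units outside
  the two-sided 95% shuffle band are excited/inhibited, with effect sizes
  in % rate change.
- **Synchrony.** Multitaper spike-field and LFP–LFP coherence over trials,
  pairwise phase consistency `PPC = (|Σe^{iθ}|² − N)/(N(N−1))` on a
  0–10 Hz grid, shank-distance coherence, and CA1 layer assignment
  (oriens/pyramidale/radiatum) from ripple-triggered laminar profiles.
- **Directed coupling.** Geweke frequency-domain Granger causality from
  OLS-fitted two-channel VARs,
  `gc(ω) = ln[S_tt/(S_tt − (σ_ss − σ_ts²/σ_tt)|H_ts(ω)|²)]`,
  for LFP–LFP and LFP–MUA pairs, band summaries (theta 3–6 Hz), and the
  trial-wise Spearman contrast between theta causality and slow-wave
  (0.5–3 Hz) power with 5th-percentile triggered averages.

## Worked example

```r
library(optotheta)

cfg <- synth_config(seed = 42, n_hp_channels = 4, n_ms_channels = 1,
                    pyr_depth = 2, n_units_per_region = 40)
ses <- generate_session(cfg)
res <- run_pipeline(ses$recording, ses$spikes, ses$protocol,
                    pipeline_config(out_dir = "demo_run", seed = 1,
                                    n_shuffles = 500))
res$band_table[, c("band", "mean_off", "mean_on", "p_fdr", "significant")]
```

```
        band mean_off mean_on    p_fdr significant
1       slow 23213.60 20516.4 2.82e-01       FALSE
2      theta  3347.19  3865.8 1.16e-10        TRUE
3 slow_gamma    53.62    51.4 2.82e-01       FALSE
4 high_gamma     5.64     5.6 6.40e-01       FALSE
```

Only the theta band gains power during the pulses (here +15.5%, FDR
p = 1.2e-10): the generator injects a 14.8% theta gain and leaves the other
rhythms untouched, and the paired contrast recovers exactly that pattern.
The same run prints:

```
ripple density: 0.318/s off vs 0.253/s on (-20.3%)
layers: oriens oriens pyramidale radiatum
MS units: 25.0% excited, 7.5% inhibited, global rate +12.7%
HP units: 20.0% excited, 5.0% inhibited, global rate +7.1%
theta GC: MS->HP 0.96 vs HP->MS 0.19; Spearman r = -0.64 (p = 0.00014)
```

Ripple density drops during stimulation (injected −17.3%, recovered −20.3%
on this session), the laminar labels match the configured probe layout, the
unit-population fractions recover the configured 21.5%/7.3% (septum) and
20.2%/4.7% (hippocampus), causality is septo→hippocampal in the theta band,
and trials with strong slow waves have weak theta transfer (negative
Spearman correlation).

`run_pipeline()` writes `events.csv`, `band_table.csv`, `units_summary.csv`,
`coherence.csv`, `ppc.csv`, `gc.csv`, `layers.csv`, contrast/density JSON
and a seeded run log; `make_report()` renders a markdown summary with
figures.  A thin CLI (`inst/cli/optotheta.R synth|run|report`) wraps the
same functions for shell use.

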