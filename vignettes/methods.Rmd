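---
title: "Models and methods behind optotheta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optotheta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`optotheta` analyses septo-hippocampal electrophysiology recorded under a
pulsed optogenetic protocol: 10-minute sessions in which a 5 s light pulse
recurs every 20 s (15 s off - 5 s on).  This vignette explains the models
and estimators, the choices made where the procedures left freedom, and what
the synthetic generator does and does not emulate.

## Conventions

Time is in seconds (double precision), sample indices are 0-based in files
and 1-based inside R, and every interval is half-open `[start, end)` — a
spike at exactly an epoch's end belongs to the next interval.  The "off"
epoch paired with each pulse is the 5 s immediately preceding the onset,
matching the pulse duration, not the full 15 s gap; pairs whose off window
would leave the session (or overlap the previous pulse) are dropped.
Recordings are stored as channel-interleaved little-endian int16 with a JSON
sidecar (`n_channels`, `rate_hz`, `dtype`, `scale_uv_per_bit`, channel
metadata); vendor acquisition formats are out of scope.

## Signal processing

All analyses run at 500 Hz; higher-rate input is low-pass filtered
(windowed-sinc FIR at 80% of the output Nyquist) and decimated.  Band-pass
filtering uses a windowed-sinc (Hamming) FIR applied forward and backward,
so the net phase response is exactly zero; the order follows the
transition-width contract `order = 3.3 * rate / transition` with a default
0.5 Hz transition at the ripple band, capped at one third of the signal
length (with a warning) on short fixtures.  A least-squares design would
differ only inside the transition band; the pass/stop behaviour asserted by
the tests is the contract.  Edge transients are suppressed by even-mirror
padding: odd (point-reflection) padding injects a DC step for oscillatory
signals, which we found can masquerade as a -30 dB stopband floor.

The ripple envelope uses a 4th-order Butterworth low-pass at 20 Hz.  Whether
that stage is one-pass or two-pass is not dictated by the procedure we
follow; we apply it forward-backward for phase fidelity of the envelope
(effective 8th-order magnitude), consistent with the zero-phase convention
of the FIR stage.

Instantaneous phase comes from the FFT-based analytic signal with phase 0 at
the cosine peak — the convention every phase-consistency number in this
package depends on.  Morlet time-frequency maps use 7-cycle complex
wavelets (temporal SD `n_cycles / (2 pi f)`), L1-normalised so ridge
magnitude tracks amplitude independent of frequency.

## Multitaper spectra

Power spectra average Slepian-tapered periodograms with time-bandwidth
product TW = 3 and `K = 2 TW - 1 = 5` tapers; on a 5 s window the half
bandwidth is `TW / T = 0.6` Hz.  The tapers are computed in-package as the
top eigenvectors of the tridiagonal matrix that commutes with the
band-limiting operator, located by bisection on Sturm counts and refined by
inverse iteration — an O(n) construction validated against an independent
reference implementation to 2e-13.  One-sided densities are scaled so their
integral over `[0, rate/2]` equals the signal variance.

A quoted configuration of "500 data points at 1000 Hz" alongside a "0.6 Hz
half width" is internally inconsistent (a 0.5 s window at TW = 3 has a 6 Hz
half width); we adopt the full 5 s epoch as the taper window, which is the
only reading consistent with 0.6 Hz.  Band summaries are the *mean* density
over the band (units uV^2/Hz), not the integral, matching how band tables
are conventionally printed.  Gamma-band work first whitens the spectrum by
multiplying the density by frequency, flattening the 1/f background.

Spike-train spectra bin each unit at 1 ms, subtract the per-epoch mean,
average multitaper spectra across epochs and divide by the one-sided Poisson
floor `2 lambda / rate^2`, so a homogeneous Poisson train is flat at 1.

Per-band on/off contrasts take one spectrum per 5 s epoch, reduce to band
means, and test the paired per-trial differences: a Kolmogorov-Smirnov
normality check on the standardised differences selects a paired t-test or a
Wilcoxon signed-rank test, and Benjamini-Hochberg FDR (the standard default
among FDR variants) is applied across the four bands (slow 0.5-3, theta
4-7, slow-gamma 20-40, high-gamma 60-140 Hz).

## Ripple detection

The detector follows the envelope-threshold scheme exactly: downsample to
500 Hz, band-pass 100-250 Hz (zero-phase FIR), rectify, low-pass at 20 Hz
(4th-order Butterworth), z-score with the whole-trace mean and SD, mark
epochs above 3.5 SD, extend each to the surrounding 1 SD crossings, and
merge any event starting within 50 ms of the previous event's end ("prevent
double detections" reads as one event, not a dropped one).  Per-event
metrics come from 7-cycle Morlet maps over 100-250 Hz: peak frequency is the
argmax of the event-averaged magnitude; the peak time (needed for triggered
averages, unspecified upstream) is the envelope maximum.  Because z-scoring
removes gain, detection is exactly invariant to rescaling the trace.

One property worth knowing: on pure Gaussian noise this pipeline fires at
roughly 0.1 events/s, not the ~0.04/s a Gaussian-envelope level-crossing
argument suggests, because the smoothed rectified envelope is right-skewed.
On realistic traces the true events inflate the normalising SD and the
false-alarm rate drops well below that.

Ripple density is reported as a peri-stimulus curve (5 s bins spanning
-15 s to +5 s around each onset) with the contrast `(on - off) / off`
computed from the mean rates in `[0, 5)` and `[-15, 0)`.

## Layer inference

The ripple-triggered laminar profile (per-channel mean LFP in +/-100 ms
around event peaks, >= 10 events) determines stratum pyramidale as the
channel maximising ripple-band RMS, requiring at least 1.5x the median RMS
as prominence (otherwise all channels stay unknown).  Sharp-wave polarity
assigns the remaining channels: the side of pyramidale whose mean +/-50 ms
deflection is positive is stratum oriens, the negative side stratum
radiatum.  Which side is "dorsal" is inferred from the polarity itself, so
the assignment is invariant to probe orientation — the point of inferring
location from the physiology rather than the channel order.  The 1.5x and
+/-50 ms values are free parameters with these defaults.

## Event-triggered unit analysis

The sliding-sweeps template spans +/-15 s around each onset in 500 ms bins
(60 bins; with these edges the first on-bin `[0, 0.5)` plays the role of the
"central" response bin).  Each trial's counts are normalised to sum to 1
(pooling before normalisation is available as a flag), trials without
spikes are skipped, and templates are averaged.  The on-window statistic is
the mean mass of the ten bins covering `[0, 5)`.

Significance uses an interval-shuffle null: each of 1000 shuffles
independently permutes the unit's inter-spike intervals and the protocol's
inter-onset intervals (both including the offset from the session start),
rebuilds both sequences, and recomputes the statistic.  The shuffle
conserves the spike count, the interval multiset and the total span
exactly.  A unit is excited/inhibited when its observed statistic leaves
the two-sided 95% band of its null — the simplest reading of "statistical
difference from shuffled data" — and the effect size is the percent change
of the on-epoch versus pre-pulse firing rate.  Population summaries report
per-unit fractions (not pooled across animals) and the percent change of
the summed population rate.

## Coherence and phase consistency

Magnitude-squared coherence averages tapered cross- and auto-spectra over
the 5 tapers and all 5 s trial segments; a single segment is rejected
(the estimate would be identically 1).  Spike-field coherence uses the
2 ms-binned, mean-subtracted spike count vector as the point-process
channel — exact point-process tapering is out of scope.  Pairwise phase
consistency filters the LFP in `f +/- 0.5` Hz around each grid point
(0 to 10 Hz in 0.25 Hz steps; the narrowest band resolving the grid),
takes Hilbert phases at spike times, and evaluates the unbiased pair
average through the O(N) identity `(|sum e^{i theta}|^2 - N) / (N(N-1))`,
which the tests verify equals the O(N^2) brute force to 1e-10.

## Granger causality

Directed coupling uses the Geweke frequency-domain measure from a
two-channel VAR fitted by OLS on mean-subtracted 5 s epochs: with transfer
function `H = (I - sum_k A_k e^{-i w k})^{-1}` and residual covariance
`Sigma`, the causality source->target is
`ln[S_tt / (S_tt - (sigma_ss - sigma_ts^2/sigma_tt) |H_ts|^2)]`,
evaluated on a 1000-point grid over `[0, Nyquist]` ("frequency resolution
1000" read as grid size, the standard toolbox semantics).  It is zero for
decoupled channels, non-negative, and exactly invariant to common channel
rescaling.  The headline configuration (order 50 on 2500 samples) is legal
but variance-heavy; the package default is order 20, with the order
exposed as a knob.  Per-condition summaries average per-trial spectra
rather than concatenating data, and the theta band for causality is
3-6 Hz.  LFP-MUA pairs use the pyramidale LFP and the region's pooled
2 ms-binned, 10 ms-Gaussian-smoothed multiunit rate.

The causality/slow-wave contrast correlates (Spearman) trial-wise
theta-band causality with slow-band (0.5-3 Hz) power and extracts the 5th
percentile subsets with their normalised spectra and z-scored
theta-filtered amplitudes aligned to the theta peak (whole-segment
z-scoring; the alternative windows are unspecified upstream).  The
correlation is a within-session quantity: pooling sessions adds
between-session offsets that dilute it toward zero, which is also why
large pooled trial counts report small coefficients.

## The synthetic generator

`synth_config()` defaults *are* the study conditions: 600 s sessions at
1000 Hz (desk-scale; all analyses downsample to 500 Hz, which still covers
the ripple band), a 14.8% on-epoch theta power gain, a 0.3 events/s ripple
rate scaled by 0.827 during pulses, septal excited/inhibited fractions
21.5%/7.3% with mean gains 1.532/0.545, hippocampal fractions 20.2%/4.7%
with gains 1.341/0.806, von Mises theta locking (kappa = 1), a 20 ms
septo-hippocampal theta lag and a -0.3 slow-wave/theta-drive coupling.
Within-class gain spread is log-normal with 10% CV (population effects are
published as mean +/- SEM only; the spread is a free parameter).

Hippocampal channels sum: a 1/f background (45 uV SD), a slow 0.5-3 Hz
band-noise oscillation (250 uV) whose envelope anticorrelates with the
theta drive, a theta rhythm (150 uV) whose frequency drifts inside 4-7 Hz,
narrowband slow- and high-gamma (30/15 uV), and parametric ripples:
Gaussian-windowed 120-200 Hz bursts (50-80 ms, amplitude 6x the ripple-band
background SD) riding a sharp wave whose polarity reverses across the
pyramidale depth and whose ripple amplitude is laminar-focal (Gaussian over
depth, SD 0.8 contacts).  Septal channels carry the same theta leading the
hippocampal copy by the configured lag.

The directed coupling is implemented as slow phase jitter on the
transferred theta: the hippocampal theta is the lagged septal oscillation
with a random phase wander whose depth tracks the drive state, so the
MS-coherent amplitude fraction equals the drive weight while theta *power*
is exactly unchanged.  This separation matters: an amplitude-coupled
implementation makes the paired on/off theta contrast and the trial-wise
causality variation compete for the same variance budget, and neither
matches its injected value.  Envelope and drift processes use spline
interpolation over Gaussian knots with correlation times of 20-25 s — at
least one pulse cycle — so paired on/off windows share their slow state.
An explicit VAR generator (`simulate_var()`) provides the closed-form
oracles for the causality estimators, separate from this realism fixture.

Spike trains are thinned inhomogeneous point processes: log-normal
baselines, von Mises phase modulation sharing the LFP theta phase, the
class gain during pulses, and a 3x rate boost inside ripple events for
hippocampal "pyramidal" units (75% of HP units; "interneurons" get 2.5x
baselines instead).  Class counts per region are deterministic
(`round(fraction * n)`), so fraction recovery is limited only by
classification error.

What the generator does *not* emulate: conductance-based biophysics,
anesthesia pharmacology (the cholinergic-blockade mode simply reverts the
theta gain to 1 after a configurable injection time), spike waveforms and
sorting artefacts, electrode drift, and cross-frequency (theta-gamma)
coupling.  Passing tests therefore validate the estimators against known
ground truth under realistic spectra and event statistics — they do not
certify performance on artefact-laden in vivo data.

## Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes (20-seed recovery runs,
8-session summaries, 1000-shuffle nulls, order-20 trial fits) were chosen
as the smallest sets at which the recovered quantities stabilise well
inside their tolerance bands.  Degenerate inputs fail loudly: constant
traces (z-score, detection), empty channel lists, single coherence
segments, rank-deficient VAR designs, sub-minimum spike or trial counts.
Ties in the causality/power ranks beyond half the trials raise a warning;
Spearman p-values use the asymptotic approximation.  The ripple refractory
merge extends the earlier event rather than dropping the later one.
Thinned ripple event times keep a 0.2 s minimum separation — large enough
to keep events distinct for the detector, small enough (checked) not to
bias the realized on/off rate ratio.
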