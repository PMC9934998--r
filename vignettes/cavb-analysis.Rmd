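---
title: "Electrophysiology and strain dyssynchrony analysis in the chronic AV-block dog model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrophysiology and strain dyssynchrony analysis in the chronic AV-block dog model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavbtools)
```

## The measurement problem

The chronic atrioventricular-block (CAVB) dog is a standard large-animal
model of acquired long-QT arrhythmia. After AV-node ablation the ventricles
are driven either by their own idioventricular escape rhythm (IVR) or by a
pacemaker from the right-ventricular apex (RVA) or biventricularly (CRT).
Weeks of bradycardic, dyssynchronous activation remodel the ventricles;
a challenge with the IKr blocker dofetilide then unmasks the reduced
repolarization reserve as Torsade de Pointes (TdP).

Experiments of this kind record, simultaneously:

* a surface ECG lead,
* ten left-ventricular unipolar electrograms (EGM) from a duo-decapolar
  endocardial catheter,
* one right-ventricular monophasic action potential (MAP) catheter, and
* (on echo days) radial strain traces for six short-axis LV segments.

`cavbtools` implements the quantitative chain from these signals to the
study-level statistics: per-beat fiducials, averaged intervals,
repolarization variability and dispersion, the activation-repolarization
coupling slope, TdP detection and the arrhythmia score, and strain
dyssynchrony. Because the underlying animal recordings are not publicly
distributable, the package ships a seeded synthetic generator that emulates
the recording set with full ground truth; all validation is against that
ground truth.

## Fiducials and intervals

**ECG.** Beats are located on a smoothed absolute-derivative envelope
(slope-based detection separates QRS from T waves by roughly a factor ten).
QRS onset/offset are the samples bounding the suprathreshold deflection on
the raw trace; the T peak is the raw maximum of the ST-T window; the T end
uses the tangent method (steepest terminal-limb tangent extrapolated to
baseline). Intervals (PP, RR, QRS, QT, Tp-e) are averaged over five
consecutive non-ectopic beats, taken from the last artefact-free stretch of
the analysis phase — mirroring measurement "before the first ectopic beat".
QT is rate-corrected with the Van de Water formula for anaesthetized dogs,
`QTc = QT - 0.087 (RR - 1000)` ms, and `JTc = QTc - QRS`. The JTc
definition is not universal; subtracting QRS from the corrected QT is the
only definition consistent with the reported quantities, so it is the
package default.

**EGM.** Local activation time (AT) is the pacing spike to the minimum
dV/dt of the electrogram in a 160 ms QRS window; derivatives are centred
differences after a 5 ms moving average, since the minimum of a raw noisy
derivative is unstable. Exact ties resolve to the earliest time. The
activation-recovery interval (ARI), the electrogram surrogate of local
action-potential duration, uses the steepest T-wave deflection: we take the
time of maximum |dV/dt| in the T window. For upright step-like T waves this
coincides with the classic maximum-dV/dt (Wyatt) point; taking the absolute
slope makes the fiducial invariant under T-wave polarity inversion, which
keeps baseline and challenge phases comparable when the T wave flips.
Electrodes 1 and 10 (most distal/proximal, P-wave interference) are
measured but excluded from all LV aggregates; LV means are over the
available electrodes 2–9 and the count used is reported.

**MAP.** RV activation time is the spike-to-steepest-upstroke interval
(raw-derivative maximum — the upstroke is steep enough that smoothing only
biases it). MAPD80 runs from the upstroke to the first crossing of
`baseline + 0.2 × amplitude` during repolarization, with the baseline the
median diastolic level before the upstroke; the fractional threshold makes
the measure invariant to amplitude scaling.

## Repolarization statistics

Short-term variability,

$$\mathrm{STV} = \sum_{n=1}^{N} |D_{n+1} - D_n| / (N\sqrt{2}),$$

is computed on RV MAPD or mean LV ARI series. The conventional "30
consecutive beats" prescription is ambiguous about whether 30 counts beats
or differences; the default uses N = 30 successive differences (31 beats)
so each summand matches the divisor, and a literal 30-beat mode (29
differences, same divisor) is selectable. For iid Normal(0, σ²)
perturbations E[STV] = σ√(2/π), which the tests verify by Monte Carlo.

Interventricular dispersion is `dMAPD = mean LV ARI − RV MAPD` and the
activation delay `dAT = mean LV AT − RV AT`. Intraventricular coupling is
the ordinary least-squares slope of per-electrode ARI on per-electrode AT;
a negative slope means later-activated regions repolarize earlier, and its
steepening under dofetilide indicates that repolarization reserve is
smallest in early-activated territory. Baseline and challenge slopes are
fitted on the intersection of electrodes valid in both phases so they stay
comparable. The single reported LV STV is computed on the
mean-across-electrodes ARI series; per-electrode series remain available
for diagnostics.

The challenge-phase measurement window ends at the first ectopic beat or
5 min after the start of infusion, whichever comes first; the baseline
window is the last clean stretch before infusion.

## Arrhythmia quantification

Maximal runs of consecutive ectopic beats form events (so events conserve
the total ectopic count). TdP requires at least 5 beats and a polymorphic
morphology; the polymorphism index combines the fraction of successive
beat pairs with opposite dominant QRS polarity and the modulation depth of
the QRS amplitude envelope, equally weighted. The 0.3 threshold separates
the generator's monomorphic runs (index ≈ 0) from rotating runs
(index ≥ 0.5) with margin on both sides. Inducibility means ≥ 3 TdP
starting within the 10 minutes after the start of infusion; the window is
half-open `(t0, t0 + 600 s]` with membership by event start, so an event
spanning the boundary is counted once.

Each event scores n + 1 points (n ectopic beats); an event that required 1,
2 or ≥ 3 defibrillations scores 50, 75 or 100 instead. The override (rather
than addition) keeps scores bounded and ordinal. The final arrhythmia score
averages the three most severe window episodes; with no episode the score
is 0 by default (related work sometimes assigns 1, so this is
configurable). Events terminated by cardioversion after > 10 s are treated
as single-defibrillation events by the virtual-experiment generator.

## Strain dyssynchrony

Six short-axis segments reduce to free-wall and septal traces by averaging
the two segments mapped to each wall; the two intermediate segments are
discarded. Peak strain (PS) is the trace maximum with sub-sample quadratic
refinement (plateau ties resolve to the earliest sample); TTP is the peak
time relative to the supplied beat reference; onset is the first crossing
of 10% of PS sustained for at least 20 ms, interpolated between samples.
The fractional onset threshold was chosen because it is invariant to
amplitude scaling; no standard operational definition of strain onset
exists. Deltas are free-wall minus septum.

## The synthetic generator

The generator is contract-driven: waveform shapes (a biphasic QRS wavelet
with a dominant first lobe, a raised-cosine/linear T wave, tanh
depolarization and repolarization steps on the EGMs, a logistic-upstroke
MAP with cosine phase-3) are implementation choices; what is guaranteed is
fiducial placement. Per beat and electrode k:

* the steepest negative EGM deflection falls at `beat + AT_k`;
* true ARI obeys `ARI_k = ARI_base + slope × (AT_k − mean AT) + ε_beat`,
  with `ε_beat ~ N(0, σ²)` iid per beat and shared across electrodes (so
  the mean-ARI series has SD exactly σ);
* after the infusion start, ARIs gain
  `gain × (1 + w × earliness_k)` where earliness is the rank-normalized
  earliness of activation (earliest = 1), ramped linearly over 5 min and
  then held — measurements are taken 5 min after the start of infusion,
  and with equally spaced electrode delays the end-of-ramp slope is
  analytically `slope_base − gain·w / AT_range`, which the per-group
  calibration inverts;
* the MAP upstroke falls at `beat + RV_AT` and its 20%-of-amplitude
  crossing at `upstroke + MAPD`;
* polymorphic runs rotate QRS polarity/amplitude with period 4
  (factors 1, −0.7, 0.85, −1), monomorphic runs do not. The dominant first
  QRS lobe gives every beat a well-defined polarity, which the TdP
  classifier relies on.

Regular beats sit at `60000/rate` ms spacing; an ectopic run suspends the
rhythm for its duration plus one compensatory cycle. One seeded RNG stream
per recording makes outputs bit-identical for identical parameters, and
`synth_ground_truth()` replays the same stream cheaply without waveform
synthesis.

The strain generator places a raised-cosine pulse, symmetric about its
peak, such that the *measured* features equal the requested parameters:
the sustained 10%-of-peak crossing falls exactly at `onset_ms` and the
peak at `ttp_ms` (the trace departs true baseline slightly earlier by
construction). This makes programmed wall parameters and extracted
features directly comparable at one-sample accuracy.

Defaults describe the study conditions: paced arms at 60 bpm, sinus rhythm
at 102 bpm, idioventricular escape near 45 bpm; 1000 Hz sampling (1 ms,
clinical EP resolution); electrode delay spreads, baseline ARI/MAPD,
per-group STV σ and dofetilide gain/gradient chosen so group means sit at
reported group values from the CAVB literature; additive white measurement noise at 2% of channel
amplitude. No noise spectra are available for these recordings, so the
noise level is a free parameter; 2% leaves slope recovery within ±0.01 and
fiducials within 1–4 ms. TdP episode counts per animal are Poisson with
λ = 3.5, 2.35 and 1.6 for IVR, RVA and CRT, chosen once so the probability
of ≥ 3 window episodes matches the observed inducibility fractions
(≈ 0.66 / 0.42 / 0.22).

## What the synthetic validation does and does not show

Passing tests show that the measurement chain is *internally correct*: it
recovers programmed fiducials within one sample on clean signals, recovers
programmed AT-ARI slopes within ±0.1 (noise-free) and ±0.3 (default
noise), reproduces scripted arrhythmia logs exactly, and its STV estimator
is calibrated. The generator does not emulate baseline wander, mains
interference, catheter micro-dislodgement, respiration, fused or multiform
ectopy, or T-wave morphologies beyond polarity inversion — so these results
do not certify performance on raw laboratory recordings. Group means that
depend on the real per-animal data (e.g. reported QTc or LV STV group
values) are intentionally out of reach: reported QTc/JTc values are per-animal
averages of corrected values, which cannot be reproduced from group-mean
QT and RR.

## Numerical choices and degenerate inputs

* All times in ms from recording start; sampling default 1000 Hz.
* Derivative estimation: centred differences after 5 ms moving average
  (except the MAP upstroke, where the raw derivative is used so that
  square-pulse edges are located within one sample).
* Sub-sample refinement: 3-point parabola at smooth extrema, skipped on
  plateaus so discrete earliest-tie-break semantics survive.
* Flat ECG errors immediately; a flat T window or missing MAP upstroke
  yields per-beat missing values, and LV aggregates report the electrode
  count actually used.
* STV refuses series with missing values or too few beats rather than
  silently padding.
* Zero-variance activation times make the AT-ARI slope undefined: error.
* Per-beat MAPD80 at default noise carries ≈ 1 ms of threshold-crossing
  error, which inflates extracted RV STV relative to the programmed σ;
  ARI-based LV STV is robust because its fiducial is slope-based on a
  smoothed derivative.

## Problem sizes

The test-suite and example runs use 30–200 s recordings at 1000 Hz (tens of
beats per phase, the minimum 31 for an STV) and cohorts of a few virtual
animals; one 150 s animal takes under a second, a 30-minute animal a few
seconds, so a full 51-animal virtual cohort completes in minutes on one
core. The Monte-Carlo STV calibration uses 3000 successive differences.

## Worked example

```{r, eval = FALSE}
p <- synth_params(rate_bpm = 60, duration_s = 120, at_ari_slope = -0.4,
                  stv_sigma_ms = 1, noise_sd = 0.02, seed = 1)
syn <- synth_recording(p)
beats <- detect_beats(syn$recording)
w <- select_measurement_window(beats, NA, "baseline")
interval_table(syn$recording, beats, c(w$start_ms, w$end_ms))

cfg <- experiment_config("CRT", n_animals = 3, duration_s = 1200,
                         master_seed = 1)
rows <- run_cohort(cfg)
summarize_group(rows)
```
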