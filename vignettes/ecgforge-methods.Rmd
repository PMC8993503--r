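---
title: "Simulating labelled 12-lead ECGs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating labelled 12-lead ECGs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgforge)
```

ecgforge is a knowledge-based ECG simulator and analysis toolkit. It produces
12-lead electrocardiogram signals together with exact per-sample wave-class
labels, renders them onto calibrated ECG paper with pixel-aligned
segmentation masks, reads signals back out of such masks, and classifies
rhythm with a fully transparent two-threshold rule. This vignette is the
package's account of the underlying models: what is simulated and how, which
parameters matter, what the numerical conventions are, and where design
choices were genuinely open.

## The labelling scheme

Every sample of every signal — and every pixel of every mask — carries one of
eight integer codes:

```{r}
wave_classes()
```

Classes 1–6 tile one cardiac cycle in temporal order (P wave, P–R interval,
QRS complex, ST segment, T wave, T–P segment). Class 7 exists for the one
collision the cycle admits: at short cycle lengths the T wave of one beat and
the P wave of the next overlap, and those samples are labelled T/P overlap
rather than forcing a winner. For all other collisions a fixed precedence
applies: QRS > T > P > segment classes. Repolarisation labels (ST, T) are
clipped at the next beat's QRS onset, so a very early beat truncates — and in
the extreme removes — its predecessor's T labels. Labels are identical across
the twelve leads, because wave timing is a property of the heart, not of the
projection.

## Signal model

The simulator is an expert system, not a biophysical model. Each beat is a
sum of smooth, compactly supported templates: raised-cosine bumps for P and
(skewed) T, and a QRS assembled from three signed sub-bumps producing Q, R
and S deflections. Hard support boundaries are the reason for this template
family: the labelled support of each wave must be exact, so templates that
decay asymptotically (e.g. untruncated Gaussians) are unsuitable.

Per-lead morphology comes from amplitude/polarity tables. Limb leads project
a frontal-plane axis onto the six standard lead angles
(I = 0°, II = 60°, III = 120°, aVR = −150°, aVL = −30°, aVF = 90°); chest
leads use fixed precordial progression factors (negative in V1, maximal
around V4–V5). This is the simplest mechanism that reproduces the six
phenotypes:

* **NORMAL** — axis 0–60°, QRS 70–100 ms.
* **LAHB / LPHB** — identical templates with the QRS axis moved to −75…−45°
  or 100…140°.
* **LBBB** — QRS duration 120–160 ms and discordant repolarisation: T
  polarity is flipped against the main QRS deflection in every lead.
* **HIGH_TAKEOFF** — concave ST elevation (profile $u^{1.8}$ on the ST
  support) of 0.10–0.25 mV in V2–V4.
* **ANTERIOR_STE** — convex elevation ($1-(1-u)^2$) of 0.20–0.45 mV in
  V1–V4 with reciprocal depression (−30% of the elevation) in II, III, aVF.
  The ST offset decays linearly across the T support so the trace stays
  continuous at the ST/T boundary.

Rhythm is either sinus (SR) or atrial fibrillation (AF). SR draws R–R
intervals from a truncated Gaussian with coefficient of variation
`rr_jitter` ≤ 0.035 (every beat carries a P wave); AF uses a gamma
distribution whose CV equals `rr_jitter` ∈ [0.20, 0.30] with a 250 ms floor,
and no beat carries atrial activity. AF baselines additionally carry a
low-amplitude (0.03–0.08 mV) 4–9 Hz fibrillatory oscillation, most prominent
in V1. The class scheme has no f-wave class, so these samples are labelled
T-P segment — the inter-beat class — rather than background; background is
reserved for "no signal at all" (image pixels off the trace).

Artefact is applied after synthesis and never relabels anything:
`voltage_scale × (signal + Gaussian noise + wander)`, where wander is a
per-lead sinusoid at `wander_freq` plus a smoothed random walk bounded by
`wander_amplitude`. Masks describe cardiac waves, not artefact; that is what
makes them usable as segmentation ground truth.

### Parameters and defaults

All free parameters are drawn per record from documented uniform ranges
(see `?sample_config`): heart rate 55–110 bpm, P 80–110 ms, P–R segment
40–80 ms, ST 80–120 ms, T 140–200 ms, P/QRS/T amplitudes 0.10–0.20 /
0.8–1.6 / 0.20–0.45 mV, noise 0.01–0.05 mV, wander 0.02–0.15 mV below
0.5 Hz, voltage scale 0.8–1.2. The fixed defaults are 500 Hz sampling and
10 s duration, chosen for interoperability with common digital ECG archives.
Every record is a pure function of its seed; dataset records derive per-record
seeds as `(dataset_seed × 48271 + index × 1009) mod (2^31 − 1)` so any record
regenerates independently.

## Image rendering

Rendering follows clinical paper conventions: 25 mm/s, 10 mm/mV, a red 1 mm
minor / 5 mm major grid, and the conventional 3×4 column-major layout
(I,II,III | aVR,aVL,aVF | V1–V3 | V4–V6) at 2.5 s per column, optionally with
a full-length lead II rhythm strip. The trace is drawn as vertically
connected column segments with **no anti-aliasing**, and the mask is
rasterised by the same routine with class codes substituted for colour.
Those two choices make the mask/trace correspondence exact by construction
and hence testable: every non-background mask pixel is a trace pixel of the
same sample. The grid never enters the mask.

The geometry is summarised in layout metadata (per-lead half-open pixel
boxes, baselines, time origins, px/s and px/mV), with 0-based pixel indices
and half-open `[onset, offset)` conventions throughout. `pixel_of()` and
`time_voltage_of()` invert each other to within one pixel of quantisation.

## Reading masks back

When layout metadata is absent, calibration is recovered by a grid search:
candidate spacings 4–20 px/mm in 0.25 steps are scored by the best-phase
alignment of a comb of columns with grid-coloured pixels, and the smallest
spacing within 2% of the top score wins. The "smallest within tolerance"
rule is what rejects harmonic multiples (a comb at twice the true spacing
also aligns perfectly; one at half the spacing only half-aligns). The
original search this contract descends from is described elsewhere; the
periodicity-scoring objective here is this package's own documented
substitute with the same contract, and recovers the spacing exactly on
images the package rendered at integer px/mm.

Signal extraction locates the trace in each mask column as the centroid of
non-background pixels (robust to trace widths above one pixel, unlike the
topmost-pixel rule), converts rows to mV through the baseline and px/mV,
fills empty columns by linear interpolation, and resamples to a fixed 500 Hz
regardless of pixel density — downstream 1D analysis expects a fixed rate.
Leads with more than 20% empty columns are returned but flagged
low-confidence. Label sequences are read per column as the modal
non-background class. With only a grid calibration and no layout, a mask
cannot be split into leads; it is then treated as a single strip at standard
calibration with the baseline estimated from the trace row profile — the
layout-driven path is the primary one.

## The rule-based AF detector

The detector consumes 1D label sequences (for 2D masks, lead II — or the
rhythm strip — is converted first). Its pipeline is deliberately inspectable:

1. **QRS clusters**: maximal runs of class 3, merging runs separated by
   < 20 ms and discarding runs < 40 ms.
2. **R–R dispersion**: population standard deviation of onset-to-onset
   intervals, in ms. Onset-to-onset because masks delimit QRS support but do
   not localise R peaks. Fewer than three clusters is signalled as
   "insufficient beats", not silently zero.
3. **P-wave search**: the 250 ms window before each QRS onset is searched
   for a class-1 run of ≥ 20 ms; the fraction of QRS complexes so preceded
   is the feature X operates on. X is interpreted as a *fraction* rather
   than an absolute count, which makes the rule invariant to recording
   length.
4. **Decision**: AF if and only if `p_fraction < X` **and** `rr_sd > Y`,
   with strict inequalities — absent atrial activity alone (e.g. a flat
   recording) or irregularity alone (e.g. ectopy) is not enough.
5. **Fitting**: X and Y are fitted by exhaustive search over
   X ∈ {0, 0.05, …, 1} × Y ∈ {0, 10, …, 300} ms (651 cells) maximising F1
   for the AF class on a validation fold, ties broken towards smaller X then
   smaller Y. The 0.05 × 10 ms resolution is finer than any plausible
   decision boundary at negligible cost, and the fixed tie-break makes
   fitting deterministic.

## Evaluation

Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and PPV `tp/(tp+fp)`
signal zero denominators as errors rather than returning NaN. The F1 score
is the harmonic mean `2·S·P/(S+P)`; a widely circulated rendering of this
formula with a product in the denominator reduces to the constant 2 and is
implemented here in corrected form (the convention F1 = 0 when S = P = 0
covers the all-negative predictor). Segmentation overlap uses the smoothed
Dice and Jaccard forms, `(2|A∩B|+s)/(|A|+|B|+s)` and `(|A∩B|+s)/(|A∪B|+s)`,
reported per class and macro-averaged over the seven wave classes; at
`s = 0` they satisfy `dice = 2·iou/(1+iou)`, which the tests exploit as an
identity check.

Dataset splitting is a seeded shuffle followed by a stratified 60:20:20
partition with cumulative rounding, so overall fold sizes are exact to one
record and per-stratum proportions track the global ones to two. The
`group_by` option assigns whole groups (e.g. all records of one subject) to
a single fold; it is off by default because record-level splitting is the
common case for synthetic data, but grouped splitting is what prevents
subject leakage on real archives.

## What the generator does and does not emulate

The generator reproduces the features the downstream components rely on:
exact wave supports, lead-consistent timing, rhythm-dependent R–R
dispersion, presence/absence of atrial activity, phenotype-specific lead
patterns, calibrated paper geometry. It does **not** emulate ectopy, flutter
or paced rhythms, respiratory modulation, electrode artefact that mimics
waves, inter-patient template variability beyond its parameter ranges, or
photographic distortion beyond the four synthetic artefact operations
(rotation ≤ 5°, blur, lighting gradient, blotches). Consequently, passing
round-trip and detector tests here demonstrates internal consistency of the
method chain on idealised data — it does not certify performance on real,
predicted (noisy) segmentation masks, where QRS fragmentation and spurious
P clusters are the dominant failure modes the `merge_gap`/`min_dur`
parameters exist to absorb.

## Problem sizes and numerical conventions

The test and acceptance workloads use the package's standard study sizes:
200 records for simulator invariants, 100 + 100 schedules at a matched
80 bpm for dispersion separation, a 200-record (100 SR / 100 AF) set with a
stratified 60:20:20 split for end-to-end threshold fitting, 1000 random
sequences for the cluster oracle, and 20 clean renders at 6 px/mm (plus
calibration probes at 6, 8, 10, 12 px/mm) for the image round trip.
Rendering for round-trip work defaults to 6 px/mm — at 25 mm/s that is
already 6.7 columns per 500 Hz sample pair, comfortably above the Nyquist
needs of the readback, and image size grows quadratically in px/mm.

Other conventions: 0-based sample and pixel indices with half-open
intervals everywhere; one seeded generator per record with documented
derived streams for scheduling, noise and artefact (so adding noise does not
perturb the schedule); float32 little-endian lead-major signal files with
uint8 label files and JSON sidecars; JSON-lines manifests.

## Known limitations

* The AF/SR feature space on ground-truth masks is near-separable by
  construction, so fitted thresholds sit close to the lattice origin; on
  predicted masks the brute-force search matters more.
* Calibration-only readback assumes standard paper settings (25 mm/s,
  10 mm/mV) and a single strip.
* The precordial tables encode one representative electrode geometry; there
  is no torso model, so phenotypes that chiefly alter the horizontal-plane
  loop (e.g. RBBB) are out of scope.
* `estimate_grid()` expects the grid colour to be distinguishable by chroma;
  monochrome grids are reported uncalibratable.
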