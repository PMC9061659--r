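---
title: "Methods: simulating and comparing perimetric threshold strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing perimetric threshold strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisim)
```

## The problem

Static automated perimetry estimates, at each of a fixed grid of visual
field locations, the dimmest luminance increment a patient can see.
Different instruments and thresholding algorithms disagree
systematically: an interpolation-based strategy that directly tests only
a subset of locations, run on an instrument with a reduced dynamic
range, will report shallower loss than an independent per-location
staircase on a full-range instrument — both because interpolation pulls
estimates toward neighbouring (often healthier) locations, and because a
reduced dynamic range clips deep defects at the instrument's floor (the
*plateau effect*). `perisim` builds this whole comparison in silico,
with observers whose ground truth is known exactly, so that each
mechanism can be isolated and measured.

## The decibel scale and the plateau

Sensitivity is expressed as attenuation of the maximum stimulus:
\[
\Delta L(\mathrm{dB}) = 10^{(k - \mathrm{dB})/10} \ \mathrm{asb},
\]
so 0 dB is the brightest presentable stimulus and the constant \(k\)
fixes that maximum: \(k = 40\) (10,000 asb) for the full-range
instrument, \(k = 30\) (1,000 asb) for the reduced-range one.  Both use
a 31.5 asb (≈ 10 cd/m²) background.  Equal physical luminances
therefore differ by \(k_1 - k_2 = 10\) dB between scales: a 0 dB
threshold on the reduced-range instrument is a 10 dB threshold on the
full-range scale, and any true sensitivity below that is recorded *at
the floor* — deep focal loss is invisible to the smaller instrument.

A note on sources: the published description of this scale gives a
formula involving the background luminance that does not reproduce its
own numeric anchors (the stated maxima and the 10 dB offset); the
implementation uses the attenuation form above, which reproduces all of
them exactly.  Likewise the maximum stimulus luminance of the
reduced-range instrument is taken as 1,000 asb (the value that carries
the plateau argument), not the 10,000 asb stated elsewhere in the same
source.

Ground truth is always stored on the \(k = 40\) reference scale;
instrument scales enter only at presentation time.  This gives a single
source of truth for cross-instrument comparison.

## Grids and sectors

The 30-2 pattern is the 6°-spaced lattice of odd multiples of 3° with
\(x^2 + y^2 \le 841\): 76 locations, two of which — (+15, +3) and
(+15, −3) in right-eye format — fall in the physiological blind spot.
The 66-location grid removes the top and bottom rows (y = ±27) and the
blind-spot pair.  All analysis is done in right-eye format (left-eye
fields are mirrored).  Six angular sectors loosely following
ganglion-cell fibre-bundle anatomy partition the grid (central < 10°,
a temporal wedge, and four quadrants that respect the horizontal
midline in the nasal field); the exact bundle geometry is not published
for the device being emulated, so a Garway-Heath-style partition is
used and is configurable.  One seed location per sector is designated;
the default seeds repair an obvious duplicate in the published example
list by midline symmetry.

## The observer model

Each observer is a ground-truth field plus a frequency-of-seeing
response model,
\[
p(\text{seen}) = fp + (1 - fp - fn)\,
\Phi\!\left(\frac{S - s}{\sigma(S)}\right),
\qquad \sigma(S) = \mathrm{clamp}(e^{3.27 - 0.081 S}, 1, 6)\ \mathrm{dB},
\]
with Henson-style spread that grows as sensitivity falls — about 2.3 dB
at 30 dB, saturating at 6 dB in deep defects.  Defaults
\(fp = fn = 0.03\), fixation-loss rate 0.05.  Setting the clamp bounds
to zero yields a deterministic step-function responder, used by the
tests to force known presentation traces.

Normal fields follow a hill of vision
\(S = 34 - 0.25\,ecc - 0.07\,\max(0, age - 20)\) dB plus spatially
correlated noise (a shared per-sector offset, SD 0.5 dB, plus 1 dB
white noise).  The slopes are conventional values for this class of
instrument; the sector offsets exist so that normals have non-zero
pattern statistics, which the deviation cut-offs need.

Cohorts emulate the two clinical groups: 39 glaucoma-like observers
(ages 54.7 ± 12.6) receiving 0–3 focal bundle-sector defects, and 31
cataract-like observers (ages 60.8 ± 9.6) receiving uniform diffuse
loss.  Focal defects subtract a constant depth inside the chosen
sector with a Gaussian edge fall-off that never crosses the horizontal
midline in the nasal field.  Defect depths (uniform 6–30 dB by
default) are chosen to *span* the severity spectrum of the emulated
study, not to match its exact category counts, which are not
reconstructable from the published summary.  Diffuse loss is gamma
distributed (shape 1.6, scale 2.2; mean 3.5 dB).  This default was
revised once during development: the emulated cataract group spans
trace to dense opacity with mean deviations reaching about −10 dB, and
the original mean of 2.5 dB underrepresented that tail.

What the generator does *not* model: light-scatter optics, pupil size,
refractive blur, fatigue across a test, and learning across visits.  A
green directional test therefore establishes that the algorithmic and
dynamic-range mechanisms alone produce the observed direction — not
that they explain its full clinical magnitude (see *Known limitations*).

## Thresholding strategies

**Staircase stand-in.** The proprietary Bayesian strategy of the
full-range device is not published in implementable detail; a classic
4-2 dB double-crossing staircase stands in for it, sharing the property
that matters for the comparison: every location is an independent
assay.  Stimuli step dimmer after "seen" and brighter after "not seen"
(4 dB until the first reversal, then 2 dB until the second); the
estimate is the last-seen level.  Start levels follow a growth pattern:
the four primary points at (±9, ±9) start at age-corrected normal,
other locations at the mean of already-thresholded 6° neighbours.  An
observer who never sees the brightest stimulus is recorded at the
floor with a saturation flag.

**Four-phase interpolation strategy.** Phase 1 directly tests only the
six seeds — the upper pair and lower pair with an alternating 4-2-1
bracket in which each member's start is informed by the other's
responses — and fills the other 60 locations from a seed regression
model (least squares from the 6 seed values to all 66, fitted to a
synthetic bank of training fields standing in for the vendor's large
normative sample; without a model, inverse-distance interpolation with
a warning).  Phases 2–4 each directly test 21 locations chosen by a
stratified round-robin over sectors.  Because 3 × 21 exceeds the 60
non-seed locations, phases 2 and 3 are disjoint and phase 4 tests the
remaining 18 plus 3 re-tests; seeds are never re-tested; every location
is directly tested at least once.  Each tested point gets a
two-presentation probe at the previous estimate and one previous
standard error away; "seen at the estimate but not at the dimmer
probe" *confirms* the estimate, the other outcomes correct it by up to
one SE (this reading of "corrections equal to the previous standard
error" was chosen so that a noiseless observer's estimates are fixed
points of every phase).  Untested locations receive the sector-wise
distance-weighted mean of the observed corrections.  The final
threshold discards the most extreme of the four per-phase estimates —
of the four leave-one-out triples, the one with minimal range is
averaged; ties prefer discarding the phase-1 estimate, then the largest
value.

Test time is reported as a presentation-count proxy
(1.5 s per presentation + 20 s overhead); only ratios are meaningful,
and the simulated ratio (≈ 0.48) reproduces the roughly halved test
time of the emulated device.

## Indices, normative databases, severity score

Normative databases are built by simulating and measuring 60 normals
per strategy/instrument with the same machinery used for patients —
so each strategy is referenced to its own normative surface, exactly as
real devices are.  Total deviation is measured minus age-corrected
normative mean; pattern deviation subtracts the general height (the
85th percentile of the TD distribution, a standard convention; the
source never defines its PD construction).  MD is the unweighted mean
of TD (a variance-weighting toggle exists but defaults off for
transparency); PSD is the RMS deviation of TD about MD; NAPDP counts
PD values below the empirical 5% cut-off.  Cut-offs use type-6
quantiles: with 50–60 normals, the usual type-7 definition flags
held-out normals at ≈ 7% instead of 5%.

The AGIS-style severity score (0–20; categories none / mild / moderate
/ severe / end-stage at 0, 1–5, 6–11, 12–17, 18–20) is computed from
the TD map on the common 66-location grid for both strategies, keeping
scores comparable.  The original defect criteria are not reprinted in
the emulated study; the packaged criteria table is a clearly-labelled
synthetic reconstruction keeping the published structure (nasal ≤ 2,
each hemifield ≤ 9 from clusters of ≥ 3 adjacent depressed sites,
graded by extent and by depth levels 12/16/20/24/28 dB), with one
deliberate change: depth points require a minimum *count* of deep
sites rather than a fraction of the cluster, because the fraction rule
is not monotone when a new, shallower site joins a cluster.  Every
threshold lives in one editable JSON file.

## Agreement battery

Bland–Altman bias and 95% limits of agreement (±1.96 sample SD, no
small-sample correction, matching the emulated analysis); proportional
bias as the OLS slope of differences on pair means with a t test on
n − 2 df (closed form, so an exactly constant difference yields exactly
t = 0); Spearman correlation on midranks with the asymptotic t
approximation; Wilcoxon signed-rank with zeros dropped, midranks,
tie-corrected variance and continuity correction (normal approximation
beyond n = 25 or under ties, exact otherwise); and per-location bias
maps over the 66 matched points.  The difference convention is fixed
as staircase − interpolation strategy and stated in the outputs.  The
rank tests are implemented from their definitions and verified against
an independent reference implementation in the test suite.

## The study pipeline

`run_study()` wires everything together: training bank → seed
regression; normative databases; cohorts; both strategies per observer
(interpolation strategy on the k = 30 instrument, staircase on k = 40,
plus an optional counterfactual running the interpolation strategy on
k = 40 to separate the algorithm effect from the dynamic-range effect);
reliability filtering (exclude if FP > 20%, FN > 20% or FL > 30%,
strict inequalities; the interpolation strategy measures no FN, so it
can never fail on FN); indices on the 66 matched locations on the
reference scale; AGIS for the glaucoma group; and the agreement
battery per group.  Everything is deterministic from one seed, every
excluded subject appears in the exclusion log with its violated
criterion, and `write_report()` emits CSV tables plus a manifest whose
fingerprint changes exactly when the configuration does.

## Numerical choices and degenerate inputs

- All RNG consumption is wrapped so that seeded calls restore the
  caller's stream; derived seeds stay below 2³¹.
- Staircases are capped at 30 presentations per location as a safety
  bound (never reached by realistic parameters).
- A degenerate seed-regression design (e.g. identical training fields)
  falls back to a small ridge penalty with a warning.
- `clip_to_range()` does not flag values exactly at the floor or
  ceiling; only true clipping sets the saturation flag.
- Zero scheduled catch trials of a type report `NA` (absent), never 0,
  so the reliability filter cannot silently pass on a rate that was
  never measured.

## Known limitations

- The clinical magnitudes of the emulated study (e.g. an MD bias of
  ~3 dB in both groups) are **not** reproduced, and cannot be from the
  published information: each strategy here is referenced to its own
  simulated normative database, which by construction absorbs
  device-calibration offsets, and the observer model contains no
  fatigue (the staircase takes twice as long in reality, which
  depresses its thresholds).  What the simulation reproduces is the
  *direction* of every reported contrast: less negative MD under the
  interpolation strategy (strongly for focal loss, weakly for diffuse
  loss), lower PSD, lower AGIS scores with a lower attainable maximum,
  and roughly half the presentations.
- The cataract-group MD direction is a small effect (≈ +0.1 to +0.4 dB)
  against the between-subject noise of a 31-subject group; it holds on
  average but not for every random seed.
- The AGIS criteria table and the bundle-sector geometry are synthetic
  reconstructions, clearly labelled as such.
- The proprietary Bayesian strategy, its timing model, and real device
  export formats are out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- study_config(seed = 1, n_normative = 50, n_training = 60)
rep <- run_study(cfg)
print(rep)
write_report(rep, "study_out")
```
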