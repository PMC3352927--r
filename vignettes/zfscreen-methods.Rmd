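---
title: "Methods: automated zebrafish cardiotoxicity and angiogenesis assays"
author: "zfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated zebrafish cardiotoxicity and angiogenesis assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscreen)
```

# Scope

`zfscreen` implements the two image-analysis readouts of an automated
zebrafish-embryo screening platform, together with the statistics used to
validate them:

* **Cardiotoxicity**: a fluorescence video of the beating embryonic heart
  (nominally 512 frames at 30 fps, cmlc2-driven GFP) is reduced to a motion
  signal, its frequency spectrum is analysed, and the embryo is classified
  as *no effect*, *bradycardia*, *2:1 atrio-ventricular arrhythmia* (the
  zebrafish signature of ERG potassium-channel blockade and hence of
  QT-prolonging compounds) or *cardiac arrest*.
* **Angiogenesis**: a fluorescence image of the trunk vasculature
  (flk1/fli1-driven GFP) is segmented, the tail region of interest is
  located, and the anti-angiogenic effect is quantified through the areas
  enclosed between the intersegmental vessels (ISVs), the dorsal
  longitudinal anastomotic vessel (DLAV) and the dorsal aorta (DA), plus
  total and complete ISV counts.

Everything is testable against seeded phantom generators whose ground truth
is computed from their parameters, never from the rendered pixels.

# Cardio pipeline

## Motion signals

The frame area is cut into square tiles (default `tilePx = 8` px;
remainder tiles at the edges keep their smaller size) and each tile is
summarised by its mean intensity. Tiling is the package's concrete reading
of "homogeneous zones": it suppresses pixel noise by a factor `tilePx`
while retaining chamber-scale motion. The **reference field** is the
temporal mean of each tile over the whole video.

For frame $t$ with tile-mean vector $x_t$ and reference $r$:

* **ED signal**: $\mathrm{ed}(t) = \lVert x_t - r \rVert_2$ — periodic
  under cardiac motion;
* **OF signal**: $\mathrm{of}(t) = \mathrm{mean}(|x_t - r|)$, a brightness
  movement measure. Its amplitude $\max - \min$ collapses to the noise
  floor when the heart does not beat. A dense optical-flow field was
  deliberately not implemented; the amplitude of this simpler measure
  carries the same arrest/no-arrest information at a fraction of the cost.

## Quality control

An embryo that drifted or twitched during recording concentrates ED power
at very low frequency. Videos whose ED power fraction below
`driftBandHz = 0.3` Hz exceeds `driftThreshold = 0.5` are flagged not
analysable and excluded from group statistics.

## Modified periodogram

The DFT periodogram of the ED signal is "modified to avoid undesired
effects" as: mean removal (kills the DC term), a Hann window (controls
leakage from residual drift), zero-padding by `padFactor = 8` (grid
spacing `fps/(padFactor*T)` ≈ 0.007 Hz at nominal settings, so the rate is
read off without parabolic interpolation), and restriction to the
physiological band `bandHz = [0.5, 8]` Hz.

## Significant frequencies

A candidate peak is an in-band local maximum. Significance requires

1. power ≥ `noiseMult` × the robust noise floor, estimated as the in-band
   median divided by $\ln 2$ (the median-unbiased estimate of the mean of
   an exponentially distributed periodogram ordinate), and
2. power ≥ `relThresh = 0.25` × the dominant in-band power.

Peaks closer than `peakMinSepHz = 0.25` Hz are merged (the padded spectrum
of a single rhythm is smooth, but noise can split one main lobe into two
local maxima). Peaks at integer multiples (±3 % relative) of the lowest
significant frequency are pruned as harmonics *unless* they clear the
`relThresh` criterion — the escape hatch that keeps a genuine second
rhythm at frequency ratio 2, which is exactly the 2:1 block signature and
is formally indistinguishable from a harmonic series by position alone.

`noiseMult` defaults to 12. A smaller conventional-looking value (8) fails
its own false-positive requirement: across the ~128 independent in-band
bins of a 512-frame video, the probability that pure noise produces no
significant peak is only ≈ 0.96 at 8 × floor, but ≈ 0.9995 at 12 × floor
($e^{-12}$ per bin). Genuine cardiac peaks exceed the floor by three or
more orders of magnitude, so the higher default costs no sensitivity.

## Classification

In order:

1. `ofAmplitude < arrestAmplitude` → **CARDIAC_ARREST** (rate 0). The
   spectrum is consulted only above this gate.
2. ≥ 2 significant frequencies → **ARRHYTHMIA_21**; the rate is the first
   (lowest) significant frequency, i.e. the ventricular rate.
3. one significant frequency $f$: $15 f < 36.5$ beats per 15 s →
   **BRADYCARDIA**, else **NO_EFFECT**. The 36.5 cutoff is the
   ROC-derived bradycardia threshold on the 15-second scale; the boundary
   itself is not bradycardic (strict `<`).
4. motion above the arrest gate but no significant peak → **NO_CALL**,
   excluded from group statistics.

`arrestAmplitude` is calibrated as `arrestNoiseMult = 5` times the OF
amplitude of a pure-noise video at the configured pixel noise SD
(simulated with a fixed internal seed). Because it is an absolute
intensity quantity, rescaling all intensities by $k$ rescales the
appropriate gate by $k$ as well; all spectral thresholds are relative and
scale-free.

# Angiogenesis pipeline

## Segmentation and ROI

The embryo mask is the largest 8-connected component of the thresholded
image after 5×5 closing. The threshold is Otsu's, computed on
5×5-box-smoothed *log* intensities: fluorescence images are trimodal
(background, faint body, bright vessels) across a wide dynamic range, and
the log compresses the vessel mode so the split lands between background
and body. Embryo length is the mask extent along its principal axis.

The tail ROI starts immediately posterior to the global maximum of the
column-wise mask-thickness profile (the yolk bulge) and runs to the
posterior tip. A profile with no recognisable bulge (peak prominence over
the median thickness < 10 %, or monotone) falls back to the posterior
60 % of the length with a warning.

## Vessel mask

Inside the ROI: white top-hat with an 11×11 box (background subtraction;
the box exceeds every vessel width so vessels pass), threshold at the
maximum of Otsu's value and a robust noise ceiling (median + 6 MAD of the
top-hat — Otsu alone would split even a pure-noise crop), 3×3 closing, and
removal of fluorescent areas that should not be quantified: only
components spanning at least half the ROI width are kept. The axial rails
always span the ROI, and every genuine ISV is connected to them, so this
implements "keep what is connected to the axial vessels" with one pass.

## Enclosed areas and counts

Enclosed regions are the topological holes of the vessel mask inside the
ROI: 4-connected background components (the complementary pairing to the
8-connected vessels) that do not touch the ROI border, of at least
`minHoleAreaPx = 9` px (pinhole guard). When vessels are incomplete or
the DLAV is absent no hole exists and nothing is measured — which is the
point of the measure: a ladder of $k$ complete ISVs under a spanning DLAV
encloses exactly $k-1$ cells, and losing any single ISV or DLAV stretch
removes at least one.

For counting, the two axial bands are located as horizontal-run maxima
(rows covering ≥ `railMinFrac = 0.3` of the ROI width): the dorsal-most
band is the DLAV, the next the DA/PCV; the pair is rejected (counts
reported missing) if they are closer than 20 % of the ROI height, which
happens exactly when the DLAV is absent and the DA/PCV pair would be
mistaken for two rails. Components strictly between the bands are ISV
candidates; height ≥ `totalFrac = 0.2` × rail separation counts toward
the total, height ≥ `completeFrac = 0.9` × separation with the top
touching the DLAV band counts as complete. The two cutoffs are not taken
from any published source and are exposed in the configuration.

## Group calls

A treated group is **INHIBITED** when its enclosed-area mean is
significantly below the vehicle control (ANOVA + Dunnett-adjusted p <
`alpha = 0.05`) — the ISV count summaries ride along as the "deeper
analysis". Statistics require at least 10 analysable embryos per group;
smaller groups are flagged and excluded.

# Statistics layer

* **Mann-Whitney U** (`mannWhitney`) is the default cardio group test —
  heartbeat distributions are left-skewed, so a rank test is preferred.
  Exact p for `min(n) ≤ 8` without ties, corrected normal approximation
  otherwise (`stats::wilcox.test` underneath). Exhaustive enumeration at
  $n_1 = n_2 = 8$ puts the worst-case exact-vs-approximate discrepancy at
  0.0109.
* **Welch t** (`welchT`) for two-group angiogenesis comparisons; the
  doubly-degenerate zero-variance case returns p = 1 (equal means) or 0.
* **ANOVA + Dunnett** (`anovaDunnett`): the omnibus F from `stats::lm`,
  and Dunnett-adjusted two-sided p values from a Monte-Carlo evaluation of
  the null max-|t| distribution (group means and the pooled variance
  resampled; ≥ 10^5 draws under a fixed internal seed, restored
  afterwards). No distributional table is needed, arbitrary group sizes
  are exact in the Monte-Carlo limit, and `k = 1` reduces to the pooled t
  test within ~0.005. A perfect fit (zero residual variance, which
  noiseless phantoms produce legitimately) is special-cased.
* **4PL fit** (`fit4PL`): variable-slope sigmoid
  $b + (t-b)/(1+(d/\mathrm{IC}_{50})^h)$ fit on log-dose with
  `nls(algorithm = "port")` (robust to the zero-residual noiseless case);
  start values from the response range and midpoint crossing;
  non-convergence is flagged, never thrown. Plate-level IC50 fits use the
  *complete-ISV count* as response: for independently completed vessels
  the enclosed-area response is approximately quadratic in the completion
  probability and would bias a logistic IC50 downward, while counts are
  linear in it.
* **ROC threshold** (`rocThreshold`): empirical sweep over all cut points,
  Youden-optimal choice. The phrase "exclusion model" in the platform
  description is non-standard; plain empirical ROC is used.
* **Validation summaries** (`confusionSummary`): note that the platform
  validation consistently calls the positive-detection rate
  "specificity" and the negative-rejection rate "sensitivity" — the
  reverse of the conventional usage. Both labellings are reported side by
  side (`asPaper`, `standard`) so the printed numbers (90.3 %/100 % for
  the cardio screen, 83 %/100 % for the angiogenesis screen) are
  reproduced without ambiguity.
* **Verdicts** (`assignVerdict`): an explicit match table transcribed from
  the 35-row cardio validation screen, not a general severity rule —
  notably, a bradycardia inducer observed as cardiac arrest counts as a
  true positive (cross-severity detection), while a QT-prolonging
  compound is detected only through the 2:1 arrhythmia.

# Phantom generators

## Heart videos

`makeHeartVideo` draws two soft-edged elliptical chambers over a static
fluorescent body; chamber radii contract once per cycle following an
asymmetric raised-cosine pulse (duty 0.6) whose phase travels across the
chamber (spread 0.3 cycles), with Gaussian pixel noise (default SD 8
against a chamber contrast of 300) and rounding to the integer camera
grid. Three deliberate choices:

* **Why a pulse, not a sinusoid**: the ED signal is a norm and therefore
  rectifies; a time-symmetric area oscillation folds all its power to
  twice the beat frequency. One asymmetric contraction per cycle keeps
  the ED fundamental at the true rate — as in real cardiac videos, where
  systole and diastole are not mirror images.
* **Why a traveling wave**: with all pixels contracting in phase the
  rectified harmonics are strong enough to mimic a second rhythm; the
  peristaltic phase spread (present in the real embryonic heart tube)
  decorrelates tile mean-crossings and cancels the folded harmonic, so a
  control phantom carries < 25 % relative power at twice its rate.
* **Amplitude ratios**: controls are ventricle-dominated
  (`ampRatio = 2`); the 2:1 regime uses `ampRatio = 0.7` — in an
  atrio-ventricular block the atrium beats fully on every cycle, and this
  keeps both spectral components above the significance threshold.

What a green test does **not** establish: the phantom has no pigment, no
focus drift, no out-of-plane motion, no pericardial edema, and its noise
is white — real-video classification rates cannot be inferred from
phantom accuracy, which is why the validation tables are shipped as data
rather than re-derived.

## Vessel images

`makeVesselImage` renders a faint body (head blob, tapering trunk, yolk
bulge at a configurable fraction of the length) and a bright vessel
skeleton: DA and PCV rails, a DLAV rail with optional gaps, and vertical
ISVs rising from the DA, truncated at mid-height when incomplete. Ground
truth (counts; enclosed regions via interval logic over complete-ISV
pairs and DLAV gaps) is geometric. Not emulated: vessel waviness and
width variation, inter-embryo anatomical variation, autofluorescent gut,
mounting artefacts.

## Dose-response

`makeDoseResponse` draws 4PL readings with Gaussian noise;
`dose == IC50` gives the exact midpoint. Validated-compound IC50 values
(0.035 µM, 2.6 µM) are used as scenario constants in tests — recovering
them from synthetic curves validates the fitting code, not the biology.

# Numerical and degenerate-input choices

* Constant videos: ED ≡ 0, OF amplitude 0 → cardiac arrest; the QC stage
  treats them as non-drifting.
* Circular time-shift of the frames leaves the category unchanged exactly
  and the rate within one padded grid bin (the Hann window breaks exact
  DFT shift invariance; the window is kept because drift suppression
  matters more than bit-exact shift symmetry).
* A beating video with no significant peak is NO_CALL, not misclassified.
* Empty foreground → `"no embryo detected"` error; an unreadable well
  image flags the well and the plate run completes.
* TIFF I/O is implemented in-package (baseline uncompressed grayscale,
  8/16-bit, multi-page, both byte orders) because the installed R stack
  offers no TIFF reader; AVI is rejected with a clear error.
* All internally seeded computations (Dunnett Monte-Carlo, arrest-gate
  calibration) save and restore the caller's RNG state.

# Known limitations

* The significance rule, periodogram modification and OF formulation are
  engineering reconstructions validated on phantoms only; the original
  platform's exact filter chains were proprietary.
* Atrium/ventricle are not spatially segmented; a 2:1 call is spectral
  evidence, not chamber-resolved.
* Vessel width is not separately quantified; thinner vessels register
  only through their effect on enclosed area.
* The ROI heuristic assumes a roughly horizontal embryo with the head on
  one side (`anteriorLeft`); strongly curved embryos would need the
  fallback ROI.
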