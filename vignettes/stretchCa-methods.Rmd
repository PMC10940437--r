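---
title: "Quantifying stretch-activated calcium signalling with stretchCa"
author: "stretchCa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stretch-activated calcium signalling with stretchCa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stretchCa)
```

## The experimental design this package analyses

Adherent cells loaded with a fluorescent Ca²⁺ indicator (e.g. Fluo-4-loaded
HL-1 atrial cardiomyocytes) are imaged on an elastomer substrate through a
four-phase protocol of one minute each:

* **P I** — pre-stretch baseline. Spontaneously active cells oscillate here;
  a mechanosensitive-channel blocker (GsMTx4) may be present from the start.
* **P II** — a chemical agonist of the Piezo1 channel (Yoda1) may be added.
* **P III** — the substrate is stretched isotropically (15 % radial stretch
  by default). Mechanosensitive channels open, admitting Ca²⁺.
* **P IV** — the stretch is released.

The camera records continuously (10 frames/s by default), so one recording
is a single multi-page stack covering all four phases. Because the chamber
physically expands during P III, the field of view shifts and scales between
the phase groups; recovering *the same cell* before, during and after
stretch is a geometric problem, not just a segmentation problem.

`stretchCa` turns such a stack into per-cell relative Ca²⁺ traces, a
rule-based response classification per cell, and per-sample summaries with
gated two-group statistics. A synthetic scene generator with full ground
truth stands in for microscope data, so the entire chain is testable offline.

## Image pipeline

**Correction.** Frames are corrected as `(frame − dark) / flat`, with the
flat field normalised to unit mean so the intensity scale is preserved, and
negative values clipped at zero.

**Phase splitting.** Frames are partitioned by acquisition time into three
groups — *pre* (P I + P II), *stretch* (P III) and *release* (P IV) — using
half-open `[start, end)` windows, so a frame exactly on a boundary belongs
to the later phase. The stretch/release boundary is where the geometry
changes, which is why the groups, not the phases, are the unit of
registration.

**Drift registration.** Within a group the deformation is modelled as pure
translation, estimated per frame by Fourier cross-correlation against a
reference frame with sub-pixel parabolic refinement. Constant (featureless)
frames cannot be registered and raise an error naming the frame.

**Segmentation.** Cells are segmented on the temporal maximum-intensity
projection of the *stretch* group, where active cells are brightest.
Foreground comes from a global Otsu threshold by default (a manual absolute
threshold can be supplied), the projection is smoothed with a 1-px Gaussian,
and touching cells are separated by a watershed seeded at regional maxima
(equal plateaus merge into one seed, making the result deterministic).
Regions below `min_area = 30` px² and regions touching the border are
removed: partial cells bias mean-intensity traces. Using the projection also
makes segmentation invariant to the acquisition order of frames.

**Cross-phase ROI mapping.** The stretch device produces an isotropic
in-plane expansion, so the dominant cross-group deformation is a similarity
transform (scale + translation about the field centre; rotation is carried
in the model but the estimator fixes it at 0). The scale is found by a
coarse 0.01-step grid search — each candidate scale is applied to the source
projection and the residual translation measured by cross-correlation — and
then refined locally on the correlation score. Label maps are carried into
the other groups through the inverse transform with nearest-neighbour
lookup, preserving label identity; ROIs that land entirely outside the
field are dropped and reported. Because ROI areas are pixel counts,
individual small ROIs carry a discretisation jitter of a few percent when
mapped across a scale change; area-ratio checks therefore look at the
distribution across cells, whose centre recovers `scale²` closely.

**Trace extraction.** For each frame, a cell's raw intensity is the *mean*
over its ROI in that frame's group coordinates. Mean (not integrated)
intensity is used because it is invariant under the area change that stretch
itself induces. Cells missing from any group are flagged incomplete and
excluded from classification.

## Trace analysis

**Normalisation.** The relative trace is `S_t / S_0`. Since many cells
oscillate spontaneously, transient peaks must not contaminate `S_0`: peaks
are pre-detected on a provisionally normalised copy (divided by the P I
median), and `S_0` is the mean of the earliest 3-s window inside P I whose
samples avoid every detected peak's rising and falling limbs, advancing in
1-frame steps. If no such window exists, `S_0` falls back to the mean of the
lowest 10 % of P I samples. The 3-s window length and the "earliest clean
window" rule are deliberate: the earliest window is closest to the true
resting state, and a deterministic 1-frame advance makes the estimate
reproducible.

**Peak detection.** Peaks are strict local maxima with topographic
prominence ≥ 0.3 relative units — the vertical distance between the apex
and the lowest contour connecting it to higher ground. Plateau maxima are
reported once at their leftmost sample. Detection runs once over the full
trace, not per phase, so prominence sees cross-phase context; phase-local
detection would inflate prominence at phase edges. Peaks are assigned to
phases by apex time. The implementation is checked against an exhaustive
brute-force prominence oracle in the test suite.

**Per-phase metrics.** Per phase: peak count, rate (peaks/min), mean peak
height, and the baseline intensity (BI). *Height* is the relative signal at
the apex, the natural reading of per-phase signal-level summaries. For
P III and P IV the metrics additionally include the maximal peak height
within the first 20 s of the phase — the initial response to stretch or
release. *BI* is estimated as the 10th percentile of the relative trace in
the window: the estimator itself is a design choice; a low percentile
tracks a sustained plateau while ignoring sparse superimposed oscillation
peaks, which is exactly the behaviour the sustained-elevation criterion
needs. It is configurable (`baseline_percentile`).

## Classification rules

Each cell receives exactly one activity class:

* **SPONTANEOUS** — at least 2 peaks during P I. (Spontaneity is judged on
  P I only; an optional switch `spontaneous_includes_pii` extends it to
  P II for users who prefer the broader reading.)
* **STRETCH_ACTIVATED** — otherwise, at least one peak in P III *or* a
  sustained baseline elevation there. The second clause matters because a
  strongly sustained response can saturate into a plateau on which at most
  one peak is detectable — without it, clear responders would land in the
  random-peaks bin.
* **RANDOM_PEAKS** — any peak anywhere, fitting neither rule.
* **NO_PEAKS** — nothing at all (dead cells or misplaced ROIs).
* **INCOMPLETE** — trace extraction failed in some phase; no markers are
  computed.

RANDOM_PEAKS and NO_PEAKS cells are flagged excluded from the response
analyses.

**Sustained elevation.** A phase shows a sustained increase when the BI of
its first third exceeds the P II baseline by `E ≥ 1.5` relative units, and
each of the two remaining thirds stays at or above `BI(P II) + 0.2·E`. All
inequalities are inclusive ("at least"), verified at exact-threshold
fixtures; a `1e-9` guard absorbs floating-point rounding at the boundary.
For P IV the reference stays `BI(P II)` — the same examination as for
P III, not a comparison against P III.

**Markers.** Between-phase baseline-elevation arrows fire when BI rises by
at least 0.1 relative units versus the previous phase (the threshold for
"an elevation" is a declared default, not a published constant); the
oscillation-increase marker for P II requires a strictly higher peak rate
than P I; P III and P IV are categorised *sustained* / *oscillating* (≥ 2
peaks without a sustained-scale baseline shift) / *neither*; and a
fewer-oscillations flag compares the P IV rate against P II.

## Cohort statistics

Per-sample summaries compute class percentages over classified cells and
response-category percentages separately within the spontaneous and
stretch-activated subsets, which may represent different physiological
states. Percentages are assessed per sample *before* pooling. Boxplot
summaries report quartiles with whiskers at the 5th/95th percentiles.

Two-group comparisons follow a normality gate: Shapiro–Wilk on each group;
if both pass at α = 0.05, a one-way ANOVA compares means, otherwise the
Kruskal–Wallis H test is used. Significance is declared at p < 0.05. The
protocol compares two groups at a time without multiplicity correction; an
optional Holm flag is provided (off by default) for users who want it. For
two groups the Kruskal–Wallis statistic is algebraically the chi-square
transform of the Wilcoxon rank-sum statistic, which the tests verify
numerically.

## The synthetic generator

The generator emulates the study conditions rather than any particular
recording:

* **Spike trains.** Oscillations are a homogeneous Poisson process per
  phase at the phenotype's rate (events closer than 2 s to a predecessor
  are thinned so transients stay resolvable). The rate is multiplied by a
  drug factor from P II onward. Each event adds a fast-rise/exponential-decay
  transient (rise ≈ 0.3 s, decay ≈ 1.5 s) with amplitude jittered ±20 % —
  the shape of an indicator transient without modelling dye kinetics.
* **Stretch responses.** *Oscillating* responders gain an extra 8 peaks/min
  during P III; *sustained* responders get a plateau of 2.0 relative units
  spanning P III (1-s onset ramp, exponential decay after release) plus an
  onset transient marking the initial response.
* **Scenes.** Cells are soft-edged discs (radius 5–8 px) placed without
  overlap; at the P III onset all positions and radii scale isotropically
  about the field centre by 1.15 and revert at release, with a small
  per-group field drift emulating chamber shift. The camera model adds a
  radial vignetting flat-field, a constant dark offset of 100 counts,
  photon-like noise (variance proportional to signal, 2 % relative at the
  nominal cell brightness of 500 counts) and Gaussian read noise, quantised
  to 16-bit. Identical seeds give bit-identical stacks.

Defaults (6 peaks/min spontaneous rate, 2 % noise, 500-count baseline) were
chosen once as plausible for indicator imaging at 10 frames/s; no
quantitative SNR figures exist to match, so they aim at testability with
realistic difficulty, not fidelity to a specific instrument.

What the generator does *not* emulate — photobleaching, dye buffering
kinetics, contraction-induced shape change, cell–cell coupling, elastic
(non-affine) chamber deformation — bounds what green tests mean: they
demonstrate that the implementation recovers known ground truth under the
stated model, not that the model captures every property of real
recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run scenes of 8–50 cells at
256 × 256 px and 2 frames/s (geometry is frame-rate independent), trace
cohorts of 100–300 cells at the full 10 frames/s, and 2 000 Monte-Carlo
repetitions for the statistics-gate calibration; these sizes make the whole
suite complete in a couple of minutes while leaving every estimate
well-resolved. Other numerical conventions: pixel-centred coordinates with
the origin at the top-left, x right / y down; half-open phase windows
everywhere; watershed seed ties merged; degenerate inputs (blank stacks,
empty foreground) return empty results with warnings rather than errors,
while genuinely uninterpretable inputs (featureless frames during
registration, all-zero traces) raise errors naming the offender.

## Known limitations

* Cross-phase mapping is restricted to similarity transforms; genuinely
  elastic deformations would need a nonrigid refinement on top.
* The rotation component of the phase transform is modelled but not
  estimated (the device produces negligible rotation by construction).
* BI and the 0.1 elevation threshold are declared estimator choices; other
  percentiles change marker rates and should be kept fixed within a study.
* Nearest-neighbour label mapping carries per-ROI discretisation jitter of
  a few percent in mapped areas for small cells.
* Per-cell pooling for signal-level comparisons retains the replicate id in
  the records but does not model cell-within-sample nesting.
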