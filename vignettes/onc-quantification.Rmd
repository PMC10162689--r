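---
title: "Quantifying optic-nerve regeneration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic-nerve regeneration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onctools)
```

This vignette explains the models and procedures behind each analysis in
`onctools`, the tunable parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
underlying assay leaves the design open.

## The assay

A focal crush severs every retinal ganglion cell (RGC) axon in one optic
nerve of a young *Xenopus laevis* tadpole whose RGCs carry a fluorescent
membrane transgene. Over about a week the distal axon segments fragment
and clear (Wallerian degeneration), the tectum loses its innervation, and
the axons then regrow and reinnervate it. The uninjured contralateral
nerve and tectum of the same animal provide the normalization for every
fluorescence readout, which cancels animal-to-animal variation in
transgene expression and imaging gain.

Conventions used throughout: pixel coordinates are 0-based with the origin
at the top-left, x rightward and y downward; pixels are isotropic and
anisotropic inputs are rejected rather than resampled (the readouts are
ratio-based and any resampling policy would be arbitrary); arc-length bins
are half-open `[a, b)` except the last, which is closed; nerve position 0
is the eye (proximal) end.

## Nerve profiles

`delineate_centerline()` recovers the nerve midline either from
user-supplied guide points (smoothed spline interpolation) or
automatically: Gaussian smoothing, Otsu threshold, largest connected
component, Zhang–Suen thinning, and the longest geodesic through the
skeleton graph. Thinning retracts a tube's skeleton by about half a
half-width at each tip, so both ends are extended along the local tangent
by half the local distance-transform value; on simulated nerves this
brings endpoint errors below 1 px and mean perpendicular deviation below
1 px at signal-to-noise ratio 5 and above.

`extract_profile()` resamples the path at `n_bins` (default 100) equal
arc-length stations and averages intensity along perpendicular segments of
half-width `half_width_um` (default 5 µm, roughly the simulated nerve
half-width; whether a real analysis should average the full nerve width or
a fixed band is a user decision, so the parameter is exposed). The
background estimate is the mean of a user background ROI when given, else
the image's 5th-percentile intensity. The percentile fallback slightly
underestimates true background in pure-noise regions (the 5th percentile
of a noisy offset sits below its mean), which inflates near-zero distal
ratios by a few hundredths; a background ROI avoids this.

`relative_profile()` divides injured by contralateral values bin-by-bin
with an epsilon guard (default 1% of the contralateral median) instead of
dropping zero-denominator bins, so profiles keep their length and can be
averaged across animals (per-animal profile first, then bin-wise across
animals). Ratios are stored linear; log-scaling is left to plotting.

`profile_metrics()` summarizes a profile relative to the crush position:
the proximal index is the maximum ratio over arc fractions
`[crush − w, crush)` and the distal index the mean over `(crush + w, 1]`,
with `w = 0.15`. The maximum (not mean) is used proximally because the
pile-up of retracting axonal material is a localized bump; the mean is
used distally because degeneration and regrowth affect the whole segment.

## Tectal innervation

`tectal_ratio()` uses mean (not integrated) background-subtracted ROI
intensity, making the ratio insensitive to ROI-area mismatch between the
two tecta. The ratio is invariant to global gain and to any additive
offset captured by the background ROI. "Complete denervation" — loss of
all transgene fluorescence — is operationalized as ratio < 0.05 (strict
inequality, threshold exposed). Between-group comparisons use a seeded
two-sided permutation test on per-animal ratios (10,000 resamples by
default).

## Kymograph motility analysis

`build_kymograph()` maps each movie frame onto the nerve path:
entry `(t, s)` is the *maximum* intensity on the perpendicular segment at
station `s`, preserving punctate particles that mean projection would
dilute. Station spacing defaults to one pixel.

`detect_tracks()` operates on the kymograph rather than the raw movie —
appropriate for 1 Hz imaging of particles constrained to the axon. Its
stages, each with the rationale for the design:

1. *Denoising*: a small 2-D Gaussian (σ 0.8 px) over the kymograph. At
   realistic particle densities most stations carry signal, so noise is
   estimated from frame-to-frame differences (slow punctae cancel out) and
   the detection threshold is the 5th percentile plus `k` (default 4)
   noise SDs, floored at 5% of the dynamic range so noise-free data do not
   admit blob tails as peaks.
2. *Peak finding*: per-row local maxima with a topographic-prominence
   filter (3 noise SDs) — noise shoulders on a blob flank have shallow
   separating valleys and are rejected without sacrificing the resolution
   of genuinely separate punctae — then 3-point parabolic refinement for
   sub-pixel position. Sub-pixel localization matters: at 1 µm stations,
   integer peaks would quantize 0.4 µm/s motion into alternating 0 and
   1 µm steps and badly bias the pause-excluded speed.
3. *Linking*: gated nearest-neighbor assignment, greedy by distance to a
   constant-velocity prediction (slope of the last ≤ 5 samples), gate
   `v_max · dt` (default `v_max` 2 µm/s). Prediction keeps identities
   through crossings. Gaps up to `max_gap` (2) frames are bridged by
   interpolation; shorter fragments than `min_track_len` (10 samples) are
   discarded.
4. *Occlusion handling*: when two particles come within the resolution
   limit only one peak exists and its position is dragged toward the blob
   centroid. Samples within `min_sep_um` of any other track — with tracks
   extrapolated a few frames past their lifespan at their boundary
   velocity, so merge windows are covered — are flagged occluded; occluded
   runs at track ends are trimmed, and occluded intervals are excluded
   from velocity estimation.

`classify_track()` labels by net displacement (last − first position):
|net| < 2 µm over the track is "stopped" (2 µm over a 60 s movie; no
community-standard threshold exists, so it is exposed and reported);
negative net (toward the eye) is retrograde, positive orthograde.
`track_velocity()` is the mean over consecutive-sample speeds |Δx|/Δt
restricted to intervals above 0.05 µm/s, so a paused run reports its
moving-phase speed; the two boundary intervals are excluded because the
detector's position smoothing is one-sided there. `motility_summary()`
treats the nerve as the replication unit: per-nerve fractions first, then
group mean ± SD; velocities pool tracks within a group.

## Trace decomposition and genotyping

`decompose_indels()` models the edited trace, over a window of 40 base
calls starting 3 bases downstream of the predicted cut (both exposed; the
offset skips cut-proximal dye artifacts), as a non-negative mixture of the
control trace shifted by every candidate indel size in `[−25, +35]`.
Channel heights are normalized per position to sum to 1 before fitting —
decomposition should weigh base identity, not local signal strength — and
the NNLS solution is renormalized to a probability vector. The control
must be near-homogeneous upstream of the cut (dominant channel ≥ 80% of
the per-position total). On noise-free mixtures of up to three alleles the
NNLS solution matches an exhaustive 0.01-resolution simplex grid search
allele-for-allele within 0.01.

The sgRNA screen passes at ≥ 80% overall indels *and* ≥ 50% frameshift
indels, both inclusive. The frameshift percentage is expressed as a
fraction of **all** sequences (not of edited sequences); that convention
makes the 80/50 pair coherent — under the other reading a spectrum could
pass the frameshift criterion with almost no editing.

Protein effects follow frame arithmetic: sizes not divisible by 3 are
frameshifts; in-frame deletions of `3k` nt remove `k` residues under a
codon-aligned assumption (alignment is not verified against a transcript,
so calls carry `boundary_verified = FALSE`).

F1 genotyping reflects *X. laevis*'s allotetraploidy: each locus has L and
S homeologs, each diploid. Per homeolog, alleles are spectrum entries at
or above `min_allele_freq = 0.2` — tolerant of trace noise around the
expected 0.5 — capped at the two largest; more than two passing alleles
flags contamination/mosaicism and a single passing allele is read as
homozygous (two copies). The functional dose counts non-frameshift copies
across all four slots, so a wild type scores 4 and a full knockout
(only frameshift alleles) scores 0.

## Retinal counting

`detect_somata()` is a deliberately simple multiscale
Laplacian-of-Gaussian detector (radius range 2–5 µm, four scales): the
scale-normalized LoG response is maximized across scales, local maxima are
thresholded at `k` MADs (default 4) above the median of the
finest-scale-smoothed image — testing smoothed rather than raw intensity
rejects single-pixel noise spikes — and thinned to a minimum separation of
the smallest radius. Points inside exclusion polygons (dissection
artifacts) are removed. It stands in for more elaborate validated counting
pipelines; its accuracy claims (recall and precision ≥ 0.95 at SNR 5 up to
~10% area coverage) are against simulated truth, not against any published
tool's output.

Ring partitions use a strict point-in-polygon interior test (boundary
points are peripheral). Colocalization is greedy nearest-neighbor matching
within 3 µm, each point used once; the matched count is symmetric in the
two sets. Positive-nucleus scoring samples a 2 µm disc at each nucleus and
compares its mean stain intensity with `k` MADs above the stain median;
both the positive fraction and the per-nucleus mean intensities are
returned, since either may be the readout of interest. Section-based
counts should be averaged per retina before group statistics.

## Behavior scoring

Percent response is `100 × responses / trials` over (by default) ten mock
collisions. The inclusion rule admits animals responding to **50% or
more** of pre-trials; the boundary is deliberately inclusive, matching the
operational definition used when pre-screening non-responders (assay
descriptions vary between "over 50%" and "50% or more"; the inclusive form
is adopted and exposed as a parameter).

## Synthetic data

Each generator is deterministic given `(parameters, seed)` and attaches a
`synthetic_truth` record. The noise model everywhere is Poisson shot noise
plus additive Gaussian read noise; SNR means peak signal amplitude divided
by read-noise SD.

* *Nerve pairs*: a soft-edged tube (quartic-exponential cross-section,
  width 10 px) along a gently curved centerline on a 512×512 px, 1 µm/px
  field; these geometry defaults exist to exercise the code, not to match
  any measured anatomy. The injured nerve is modulated by a raised-cosine
  proximal bump peaking at `proximal_amp` over arc fractions
  `[crush − 0.15, crush)` and a distal multiplier of 1 up to
  `regrowth_front` and `distal_residual` beyond. Named states span the
  time course: day 1 = (3.0, 0.3, crush), day 3 = (2.0, 0.05, crush),
  day 7 = (1.1, 0.9, 1.0).
* *Tectum pairs*: two ROIs at background + b and background + ratio·b.
* *Transport movies*: 60 frames at 1 Hz; stopped particles jitter with
  0.2 µm SD; movers draw a per-particle speed from a truncated normal
  (defaults 0.4 ± 0.1 µm/s) with sign by class, and start positions keep
  the trajectory on the path. Particles are placed uniformly with a 2 µm
  hard-core exclusion at t = 0: mitochondria are extended organelles
  (~1–2 µm) that cannot overlap, and point particles placed arbitrarily
  close would be unresolvable by any detector at the imaging resolution.
* *Traces*: one-hot channel heights over a random reference; deletions
  remove bases at the cut, insertions insert random bases; the edited
  trace is the frequency-weighted mixture plus Gaussian peak noise.
* *Flatmounts*: somata as σ = 2 px Gaussians on a disc retina, placed
  uniformly inside/outside a circular birth-date ring with a 6 px minimum
  separation (central points keep clear of the ring by that margin so the
  partition truth is unambiguous); an optional stain channel marks a
  random subset.

What the simulations do **not** emulate: optics-accurate point-spread
functions, photobleaching, motion artifacts, autofluorescence gradients,
tissue deformation between imaging days, or base-caller artifacts in
traces. Passing recovery tests therefore demonstrates that the estimators
are correct under the stated noise and geometry models — not that they are
robust to every failure mode of real microscopy; the config-exposed
thresholds are the levers for adapting to real data.

## Problem sizes and tolerances

The recovery suites run at desk scale: six simulated nerves × 100
mitochondria for motility (fractions recovered within ±0.05, class mean
velocity within ±10%), 100 seeded noise-free mixtures for the
decomposition/grid-search equivalence (agreement within 0.01 per
frequency), 500-soma flatmounts for counting (recall/precision ≥ 0.95,
partition within ±2%), and single nerve pairs per degeneration state
(day-3 distal index 0.05 ± 0.03, proximal index ≥ 1.5). These sizes give
binomial/sampling error comfortably inside the stated tolerances while
keeping a full run to a few minutes on one CPU.

## Known limitations

* The centerline tracer assumes one elongated structure per image; two
  touching nerves would skeletonize into one component.
* Kymograph tracking is 1-D by construction; particles that leave the
  perpendicular band reappear as new tracks.
* The dense-field velocity estimate retains a small negative bias
  (crossing residue) of a few percent at 100 particles per 600 µm.
* Trace decomposition assumes a single cut site and indel sizes within
  the configured window; complex alleles (multi-site, substitutions) fold
  into the nearest size class.
* `aa_deleted` assumes codon alignment; a transcript-aware check is out
  of scope.
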