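---
title: "Quantifying FAF features: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FAF features: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fafquant)
```

## The problem

Inherited retinal diseases (IRDs) produce characteristic signatures on
blue-light fundus autofluorescence (FAF) imaging: atrophic patches of
*definitely decreased* autofluorescence (hypo-AF), abnormally bright
hyper-AF, the perimacular hyper-AF ring typical of retinitis pigmentosa,
attenuation of the vessel tree, and the always-dark optic disc. Measuring
these features — how large they are, where they sit relative to the fovea,
and how fast they change — turns FAF into a quantitative biomarker for
genotype–phenotype analysis and progression monitoring.

`fafquant` implements that measurement pipeline with a deterministic,
rule-based segmenter in place of a learned model, and a synthetic phantom
generator standing in for hospital imaging data. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the phantoms do and do not emulate, and the numerical choices made where
the design was genuinely open.

## Image model and calibration

A `faf_image` is a grayscale matrix normalized to $[0,1]$ with an isotropic
physical scale (mm/pixel), a fovea coordinate, laterality, acquisition date
and identifiers. The scale is a required per-image input: absolute FAF
calibration depends on the device and refraction correction, so no constant
is assumed. The phantom default is 0.0214 mm/px on a 768×768 canvas,
i.e. a ≈16.4 mm field — what a 55° macula-centered scan covers on an
emmetropic eye. The fovea defaults to the image center, appropriate because
non-macula-centered scans are exactly what the pipeline's QC stage
discards; a per-image override is supported.

All areas are *pixel count × (mm/pixel)²*. This makes area estimates exact
up to rasterization: a rasterized disk of radius $r$ differs from $\pi r^2$
by at most roughly its perimeter in pixels times the pixel area, which is
the tolerance the tests use.

## Fovea-centric geometry

Distance maps are Euclidean distances from pixel centers to the fovea,
in mm. Annulus profiles partition a feature's area into half-open bins
$[kw, (k+1)w)$ with $w = 0.5$ mm by default, the last bin extended to the
image's maximal fovea distance, so the bins form a partition and the
proportions sum to one whenever the feature is present. Fixed-radius areas
use a strict inequality (distance < radius). The package computes
*per-image* profiles; averaging profiles across a cohort (versus pooling
areas before normalizing) is left to the caller, and the analysis scripts
average per-image proportions, the choice that weights patients equally.

Ring completeness bins the angular positions of mask pixels about the
fovea into 360 one-degree sectors (finer resolution would be below
annotation precision) and reports the occupied fraction. The protocol's
"more than 50% of a complete circle" is enforced strictly: coverage of
exactly 0.5 — a perfect half-annulus — is *not* a ring.

## Morphometrics

Connected components are 8-connected by default, the standard choice for
blob-like lesions. An opt-in watershed mode splits touching blobs using
the distance transform with local-maximum markers (`marker_tolerance`
controls the minimum marker depth in pixels); the plain 8-connected count
is the reference behaviour because the watershed variant has free
parameters a grading protocol does not pin down. Brightness is the mean of
raw normalized intensities under the mask — deliberately *without*
vignetting correction, since the measured quantity is defined on the image
as acquired. Vessel density is the vessel-pixel fraction of the whole
image.

## Agreement validation

The Dice coefficient $2|A\cap B|/(|A|+|B|)$ scores segmentation overlap.
When both masks are empty the score is 1 by convention but flagged, and
aggregate statistics exclude such pairs by default: summaries are
conventionally reported only over images where the feature was gradable.
Detection metrics treat the grader as ground truth and the model as
prediction; precision or recall with an empty denominator is reported as
`NaN`, never 0, so downstream averages cannot silently absorb undefined
values.

## The rule-based segmenter

The segmenter operationalizes the grading protocol's verbal definitions as
explicit rules. It makes no claim to replicate grader behaviour on real
images — the protocol's "50% grader confidence" has no pixel analogue —
but it is deterministic, testable, and honors every quantitative clause:

- **Background** ("physiological normal"): a radial polynomial in even
  powers of the normalized center distance (default order 2, i.e. $r^2$
  and $r^4$, matching the vignetting families used in fundus photography),
  least-squares fit to the median-filtered image with two
  residual-trimming passes (2.5 MAD) so lesions do not drag the fit.
- **Disc**: dark candidates below `dark_frac` (0.5) of the background,
  opened and hole-filled; the largest component passing gates on area
  (0.8–8 mm²), elongation (minor/major ≥ 0.45) and a nasal-third centroid
  wins. An empty mask is a meaningful output — it is the QC signal.
- **Hypo-AF**: relative darkness $d = (b - I)/(b - \bar{I}_{disc})
  \ge 0.9$ formalizes "at least 90%–100% as dark as the optic disc"
  against the spatially varying background $b$. The disc plus a 0.3 mm
  peripapillary margin is excluded (peripapillary atrophy is not hypo-AF
  under the protocol), and components under 20 px are dropped as speckle.
  The rule is monotone in the threshold by construction.
- **Hyper-AF**: $I \ge b(1+k)$ with $k = 0.25$ as the default margin — the
  protocol only says "brighter than the physiological normal", so $k$ is
  the main sensitivity knob and is exposed as such. The ring is excluded,
  as is sub-threshold speckle and (optionally) fleck-sized components.
- **Ring**: bright candidates restricted to a 0.5–4 mm macular window
  (approximating "within the vascular arcades"), morphologically closed to
  bridge vessel crossings, with compact components subtending under 60°
  discarded; the survivors count as a ring only if their angular coverage
  strictly exceeds 0.5.
- **Vessels**: a multi-scale black top-hat (grayscale closing minus image
  over disc-shaped elements of 5–13 px, spanning vessel calibers) gives a
  dark-tubularity response, thresholded at 20% of the local background;
  components not reachable from the disc within a 6 px gap tolerance are
  dropped, implementing "stemming from the optic disc".

Mutual exclusivity mirrors the protocol: ring ∩ hyper-AF = ∅ and
disc ∩ hypo-AF = ∅, both in the segmenter's outputs and in the phantom's
ground truth.

## The phantom generator

Phantoms exist to give every stage exact ground truth, not to be
photorealistic. A phantom renders, in order: the vignetted background, the
ring (a fovea-centered annulus, brightness ×1.4), hyper-AF disks (×1.5),
the dark elliptical disc near the nasal edge (darkness 0.85), hypo-AF
disks whose darkness is expressed *relative to the rendered disc* exactly
as the grading rule reads it, a recursive bifurcating random-walk vessel
tree seeded at the disc with caliber decay per branch level, and additive
Gaussian noise (σ = 0.02 by default). Vessels are drawn last because real
vessels overlie lesions; ground-truth masks are the pre-occlusion
geometry.

What the phantoms do **not** emulate: speckle and registration artifacts,
acquisition physics, grader disagreement, anatomical variation of the
arcades, or the intensity statistics of real lipofuscin distributions.
Passing tests therefore demonstrate that the *pipeline machinery* is
correct and that the rules behave as specified on images that satisfy the
protocol's premises — they say nothing about segmentation accuracy on real
FAF images, which is exactly the gap a learned model fills.

Longitudinal series solve the ring radius (area = completeness · 2πRw) or
scale lesion radii so the analytic area follows $a_0 + \beta t$ at the
*realized* acquisition time (dates are whole days; the model is evaluated
at days/365.25), which makes noise-free slope recovery exact rather than
exact-up-to-calendar-rounding. Areas are clamped at zero with a warning if
a negative slope exhausts a feature.

Cohort simulation draws per-patient baselines, slopes and ages from
per-gene normal distributions (truncated at zero where areas are
concerned), shares baseline and slope across the two eyes, adds per-scan
measurement noise, and can inject disc-absent scans and same-day repeat
scans to exercise QC and dedup. A metrics-only fast path skips rendering.

## Cohort pipeline conventions

- Pipeline order is QC → daily dedup → downstream; dedup is idempotent.
- "Time since first appointment" is days/365.25 from the patient's first
  retained visit; slopes are per-eye OLS, averaged (unweighted) across a
  patient's eligible eyes (≥ 2 distinct dates; no minimum span by default,
  though a span threshold is exposed).
- First-presentation records average the two eyes on the earliest retained
  date, matching per-patient reporting; per-eye records are available.
- Age bins are half-open with the boundary in the older group (30 →
  30–45, 45 → over-45), resolving the overlap in conventional labels.
- ABCA4 grouping: two severe alleles → A; a mild allele in trans with
  *any* other allele (unknown included, reading the rule literally) → C;
  remaining known-severity combinations → B; anything else unclassified.
  The groups partition every cohort.
- Per-gene summaries use patients as the unit and report mean, sample SD
  and SE = SD/√n; a single-patient gene reports `NA` dispersion rather
  than 0.

## Simulation settings used in tests and the acceptance script

Slope-recovery experiments use 100 patients (200 eyes), five annual
visits, 0.2 mm² per-scan noise and a seeded ring slope of −0.178 mm²/year;
with these settings the Monte Carlo standard error of the recovered mean
slope is ≈ 0.005 mm²/year, an order of magnitude below the 0.02 check.
Cross-sectional recovery uses 200 patients per gene at SD 5 mm². The ABCA4
severity arms use the published arm sizes (69/75/184) with between-patient
slope SDs of 1.5/1.5/1.0 mm²/year: published arm SDs describe dispersion
of *estimated* slopes, which folds in regression noise from few visits;
using them as true between-patient dispersion would push many trajectories
through the zero-area floor and censor the very linearity the experiment
probes. The age-trend demonstration uses 1000 patients with 0.005 mm²
repeatability noise so the seeded 691 μm²/year slope is recovered with
≈ 7 μm²/year Monte Carlo error. Phantom-segmentation checks run one
768 px phantom in the acceptance script and 384 px phantoms (same 16.4 mm
field, coarser grid) in the test suite.

## Known limitations

- The segmenter's thresholds are stand-ins for grader judgment; on real
  images they would need calibration against annotations, and no such
  claim is made.
- The background model is radially symmetric; strongly asymmetric
  illumination would bias the relative-darkness rule.
- Vessel segmentation targets density only; caliber, tortuosity and
  fractal metrics are out of scope.
- Axial-length differences between eyes are not modelled: areas assume the
  nominal mm/pixel scale is correct per image.
- Progression uses independent per-eye OLS; mixed-effects longitudinal
  modelling is deliberately out of scope.
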