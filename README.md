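# fafquant

Quantitative analysis of fundus autofluorescence (FAF) imaging features in
inherited retinal disease (IRD) cohorts.

Blue-FAF imaging captures the lipofuscin signal at the level of the retinal
pigment epithelium, and IRDs leave characteristic footprints in it: areas of
definitely decreased autofluorescence (hypo-AF, a proxy for RPE atrophy),
abnormally bright hyper-AF, the perimacular hyper-AF ring of retinitis
pigmentosa, the dark optic disc, and the retinal vessel tree. `fafquant`
implements the full quantitative pipeline a grading protocol for these five
features implies — segmentation by explicit rules, per-feature morphometrics,
agreement validation, fovea-centric spatial profiles, and cohort-level
cross-sectional and longitudinal statistics — together with a synthetic FAF
phantom generator that renders images with exact ground-truth masks, so that
every stage is testable end to end without access to hospital imaging data.

## What it computes

For a binary feature mask $A$ aligned to a calibrated image
($s$ mm/pixel):

- **presence**: any set pixel; **area**: $|A| \cdot s^2$ mm²;
  **components**: 8-connected count (optional watershed splitting of
  touching blobs); **brightness**: mean intensity under the mask;
  **vessel density**: $|A| / (\text{image pixels})$.
- **Dice similarity** between two masks:
  $D = 2|A \cap B| / (|A| + |B|)$, plus presence/absence detection
  accuracy, precision and recall from the 2×2 image-level tally.
- **Geometry about the fovea**: per-pixel distance maps, the distribution
  of a feature's area over 0.5 mm annuli, area within a fixed radius
  (1.5 mm ≈ inner 3 mm ETDRS ring), and angular completeness of ring
  candidates (a ring must subtend *more than* 50% of the circle).
- **Rule-based segmentation** operationalizing the grading protocol:
  background model (radial polynomial capturing vignetting), disc as the
  largest dark elliptical nasal component, hypo-AF as pixels at least 90%
  as dark as the disc relative to background (peripapillary zone
  excluded), hyper-AF as pixels ≥ 1.25× background (ring excluded), ring
  via the completeness gate, vessels via multi-scale black top-hat
  filtering with disc connectivity.
- **Cohort pipeline**: QC (drop scans with no detected disc), per-day
  dedup (keep the most recent scan per eye-date), first-presentation
  cross-sections aggregated by gene and age group, per-eye OLS progression
  slopes (mm²/year vs years since first appointment) averaged per patient,
  ABCA4 two-allele severity groups (A/B/C), and the RPGR amino-acid
  600–940 / >940 region split.

## Worked example

```r
library(fafquant)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 768x768 @ 0.0214 mm/px
seg <- segment_features(ph$image)
sapply(names(seg), function(f) round(as.numeric(dice(seg[[f]], ph$masks[[f]])), 3))
#>     disc  hypo_AF hyper_AF     ring  vessels
#>    1.000    0.985    0.979    0.993    0.965

quantify(ph$image, ph$masks)[, 1:4]
#> # A tibble: 5 x 4
#>   feature  present area_mm2 n_components
#>   <chr>    <lgl>      <dbl>        <int>
#> 1 disc     TRUE       2.38             1
#> 2 hypo_AF  TRUE       4.08             2
#> 3 hyper_AF TRUE       0.951            1
#> 4 ring     TRUE       5.04             1
#> 5 vessels  TRUE      10.6              1
```

The Dice row says the rule-based segmenter recovers each rendered feature
almost exactly on a clean phantom (1.0 = perfect overlap); the metrics
table is the per-feature record the cohort pipeline consumes — e.g. the
two seeded hypo-AF lesions of combined analytic area 4.08 mm² (2 π r²
disks) are measured at 4.08 mm² with 2 connected components, and the ring
(analytic 5.03 mm²) at 5.04 mm².

A longitudinal run:

```r
ser <- generate_series(phantom_spec(seed = 1), c(ring = -0.178),
                       visits = 5, render = FALSE)
# per-visit ring areas: 5.027, 4.849, 4.671, 4.492, 4.315 mm^2
```

fed through `progression_rate()` returns a patient slope of −0.178
mm²/year to machine precision.

The `analysis/` directory holds the numbered workflow drivers
(`01_phantom.R` … `05_progression.R`) that render phantoms, validate the
segmenter, compute spatial profiles, and run the cross-sectional and
longitudinal cohort analyses, writing their tables under `results/`.

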