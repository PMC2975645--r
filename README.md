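# nirquant

Quantification of planar near-infrared (NIR) whole-body fluorescence images
of small animals.

## The problem

Planar NIR imaging of mice injected with a targeted contrast agent (here the
motivating case is quantum-dot-loaded, antibody-decorated PEG–PE micelles
accumulating in flank tumors) yields 2-D intensity images whose raw pixel
values are not comparable across animals or timepoints: overall image
luminosity varies per acquisition, every tissue adds intrinsic
autofluorescence, and scattered light from internal organs surrounds every
region of interest. `nirquant` implements a normalization and scoring
pipeline that turns such images into a single comparable statistic per organ
and timepoint, plus the descriptive analyses that go with it (cumulative
pixel histograms, white-field composite overlays, and an ex vivo lung
melanoma-node localization index). Because animal images of this kind are
rarely deposited, the package ships a synthetic mouse-phantom generator with
fully known ground truth, so that every step of the quantification is
validated by parameter recovery rather than by eye.

## The statistic

For each image the pipeline computes, per region of interest (ROI) *r*:

1. **Hip normalization** — a reference ROI over the hip (autofluorescence
   only) is scaled to a fixed level *R*:
   `f = R / mean(I[hip])`, `I' = f · I`. This removes per-image global
   luminosity differences; every downstream value is invariant to both the
   incoming luminosity and the (arbitrary) choice of *R* (default 100).
2. **Autofluorescence baseline** — `A = mean(I'_control[body])` from a
   pre-injection or uninjected control, hip-normalized the same way.
3. **Scattered-light background** — a morphological annulus around the ROI
   (default 3–10 px, Chebyshev metric), inside the body and excluding all
   other named ROIs.
4. **Normalized signal-to-noise ratio** —

   `SNR(r) = ( mean(I'[r]) − A ) / sd(I'[annulus(r)])`

   i.e. the autofluorescence-corrected ROI mean in units of the
   scattered-light SD near the ROI. An alternative reading,
   `mean_ratio` mode, divides by `mean(I'[annulus(r)]) − A` instead; both
   are first-class and config-selected.

Cohort tables report mean ± SD (sample SD across subjects) per region and
timepoint. The ex vivo analysis scores lungs bearing melanoma nodes with a
**localization index**: the ratio of the baseline-corrected mean over node
rims to that over the remaining parenchyma (≈1 when fluorescence is diffuse,
≫1 when it concentrates around the nodes).

## Worked example

```r
library(nirquant)

truth   <- PhantomTruth()                       # default study conditions
control <- generatePhantom(uninjected(truth), t = 0)
cohort  <- generateCohort(truth, nSubjects = 5, timepoints = c(1, 2, 4),
                          seed = 42)
tct <- biodistribution(cohort,
                       control = list(image = control$image,
                                      regions = control$regions))
cohortSummary(tct)
```

```
   roi_name timepoint_h mean_snr sd_snr n
1    kidney           1   33.816 19.210 5
2    kidney           2   39.220 22.280 5
3    kidney           4   47.767 26.751 5
4     liver           1    5.418  2.394 5
5     liver           2    4.924  2.253 5
6     liver           4    4.182  1.954 5
7      lung           1   16.720  8.818 5
8      lung           2   13.550  7.090 5
9      lung           4    9.871  5.111 5
10   spleen           1   19.600  6.596 5
11   spleen           2   21.448  7.218 5
12   spleen           4   23.435  7.743 5
13    tumor           1  199.842 22.140 5
14    tumor           2  205.742 22.799 5
15    tumor           4  197.735 22.269 5
```

The tumor dominates every organ, its SNR is practically unchanged between
1 h and 4 h (the plateau built into its uptake/washout kinetics), the liver
scores lowest, and the kidney is the most variable organ across subjects —
the qualitative biodistribution pattern this kind of targeted agent shows.

The pixel-distribution contrast behind the composite-figure analysis:

```r
g    <- generatePhantom(truth, t = 1)
norm <- hipNormalize(g$image, hipReferenceROI(g$regions))$image
tum  <- regionMask(g$regions, "tumor")
body <- regionMask(g$regions, "body")
e    <- sharedBinEdges(norm, tum, body)
distributionContrast(cumulativeHistogram(norm, tum,  edges = e, maskName = "tumor"),
                     cumulativeHistogram(norm, body, edges = e, maskName = "body"))
#> $meanRatio  9.78      # tumor pixels are brighter ...
#> $sdRatio    0.783     # ... and their distribution narrower
#> $separable  TRUE
```

A command-line wrapper for shell pipelines lives at
`inst/scripts/nirquant.R` (subcommands `simulate`, `segment`, `quantify`,
`report`).

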