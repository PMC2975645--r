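---
title: "Quantifying planar NIR mouse images: model, phantom, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar NIR mouse images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirquant)
```

## The measurement problem

Planar whole-body NIR fluorescence images of mice are acquired on a
cooled-CCD station (710 nm excitation / 790 nm emission here) at several
timepoints after injecting a fluorescent contrast agent. Three confounds
stand between the raw pixels and a biologically meaningful comparison:

* **Global luminosity** differs between acquisitions and animals
  (positioning, exposure, anesthesia depth), multiplying every pixel.
* **Autofluorescence**: tissue fluoresces on its own; an ROI mean is
  meaningless without subtracting this baseline.
* **Scattered light**: NIR photons scatter through tissue, so every organ is
  surrounded by a diffuse halo originating from nearby structures; this, not
  detector noise, is the practical noise floor for deciding whether an ROI
  is genuinely enhanced.

The pipeline addresses each confound in order: hip-reference normalization
(a patch over the hip carries essentially pure autofluorescence, so scaling
it to a fixed level *R* removes the multiplicative luminosity term),
autofluorescence subtraction using a hip-normalized uninjected or
pre-injection control, and a near-ROI background annulus whose pixel SD
serves as the noise reference. The resulting statistic,

$$\mathrm{SNR}(r) = \frac{\overline{I'}_r - A}{\mathrm{sd}(I'_{\mathrm{annulus}(r)})},$$

is unitless, invariant to global luminosity and to the choice of *R*, and
comparable across subjects and timepoints.

### The two SNR modes

The background term can be read two ways: as a *noise* (the SD of the
scattered light near the ROI) or as a *level* (its mean above baseline).
"Background noise" names a noise, so `noise_sd` is the default; the
`mean_ratio` mode — $(\overline{I'}_r - A)\,/\,(\overline{I'}_{bg} - A)$,
guarded by $\varepsilon = 10^{-9}R$ — is provided as the alternative
reading and is selected per call. This is the single most consequential
modelling choice in the package; both modes are first-class. Note that the
`mean_ratio` denominator can approach zero (or go negative) for ROIs whose
annulus touches the body silhouette, where the local mean falls below the
body-average baseline; the two modes are only expected to rank ROIs
identically when every annulus sees a comparable structural background
(the rank-agreement test constructs exactly such a geometry).

### Other numerical conventions

* Pixel statistics use the **population** SD (divide by $n$); cohort
  summaries use the **sample** SD across subjects (the error-bar
  convention for N animals).
* Negative SNR values are reported, never clipped — clipping would bias
  cohort means upward.
* Thresholding is strict (`>`), so a constant image yields an empty
  detection instead of an all-body ROI.
* Masks are whole-pixel sets on R's native 1-based (row, column) grid;
  there is no sub-pixel geometry.
* Dilation (annuli) and connectivity (components) use the Chebyshev /
  8-neighbor convention throughout.
* A missing ROI at one timepoint drops that row with a logged reason; the
  time-course table is still produced.
* Intensities are assumed linear (no gamma correction), the convention for
  scientific CCD exports.

## ROI detection

ROIs are determined by threshold analysis against a reference image: the
working image is the **pixelwise minimum** of the image and the reference
(in the laboratory workflow the reference is the same subject re-imaged
with the skin removed, which eliminates skin scattering; in phantom
workflows it is the noise-free ground-truth frame). A candidate region must
therefore be bright in *both* frames. Otsu's between-class-variance
threshold (computed within the body mask, exactly over the distinct pixel
values, quantized to 256 levels only above that) is the default; a quantile
threshold is available since the original analysis software's threshold is
unknown. Components smaller than 25 px are discarded — small bright specks
are typically residual hairs after depilation, and the phantom can generate
such specks (`hairSpecks`, off by default). Organ ROIs in real-data
workflows are expected to be user-annotated; detection is aimed at bright
tumor-like regions, seeded or ranked by mean intensity. One RegionSet may
be applied across all of a subject's timepoints (the phantom cohorts do
exactly this), or detection may be re-run per image; the choice is the
user's.

## The synthetic phantom

No animal images accompany this kind of study, so validation rests on a
generative phantom whose every parameter is known:

$$I = \mathrm{Poisson}_{g}\!\Big(L\big(A_0\,\mathbf{1}_{body} +
\textstyle\sum_r c_r(t)\,\mathbf{1}_r\big) * G_{\sigma}\Big) +
\mathcal{N}(0, \sigma_{read}),$$

with mono-exponential uptake/washout kinetics
$c_r(t) = c_{max}(1-e^{-k_{in}t})\,e^{-k_{out}t}$, a Gaussian scattering
PSF $G_\sigma$, and per-image luminosity $L$. This is the *minimal* model
under which every quantification step has a recoverable ground truth:
additive region amplitudes make ROI means linear in the truth, the PSF
creates the scattered-light halos the annulus SD measures, and a
multiplicative $L$ is exactly the disturbance hip normalization exists to
remove (a global scale factor is the only reading under which that
normalization makes sense).

### Default study conditions

The defaults describe a 120 × 200 px side-view mouse at roughly 2.2 px/mm:

| parameter | default | rationale |
|---|---|---|
| tumor | disc r = 13 px, $c_{max}$ 400, $k_{in}$ 3/h, $k_{out}$ 0.02/h | superficial flank tumor; the kinetics plateau over 1–4 h (signal change < 1%) |
| liver / kidney / spleen / lung | 25 / 45 / 40 / 30 | internal organs, optically attenuated in the side view where only the tumor is prominent |
| hip reference | disc r = 8 px, $c_{max}$ 0 | pure autofluorescence |
| $A_0$ | 20 | uniform body autofluorescence |
| PSF $\sigma$ | 1.5 px (≈0.7 mm) | superficial-tissue scattering at this resolution |
| detector | gain 2000 counts/unit, read SD 0.05 | low-noise cooled CCD: the background SD is dominated by scattered-light *structure*, not detector noise |
| cohort jitter | $L \sim$ lognormal $\sigma_{\log}=0.2$ (mean-one); amplitudes lognormal $\sigma_{\log}=0.1$ (kidney 0.5); centers ±1 px | between-animal variability; the kidney is deliberately the most variable organ |

Amplitudes are arbitrary intensity units; only ratios and normalized
statistics are meaningful. All jitter distributions are mean-one, so a
cohort is centered on its base truth. Sub-seeds derive deterministically
from the cohort seed: identical seeds give byte-identical cohorts.

The detector model deserves a note. With a gain of 2000 counts per
intensity unit, shot noise at autofluorescence level is ≈0.1 unit against
scattered-light spatial SDs of 1–3 units, so the annulus SD measures tissue
structure. This is deliberate: the SNR's denominator is *defined* as the
scattered light near the ROI, and a phantom in which detector noise
dominated that term would be validating the wrong quantity — the cohort
mean SNR would also be biased a few percent below the noise-free value
(the SD inflates in quadrature), defeating parameter-recovery testing.
With the low-noise model the residual bias (≈−1%, from the concavity of
the SNR in the jittered amplitude) sits within the Monte-Carlo error of a
20-cohort experiment.

### The ex vivo lung phantom

Excised lungs from a lung-metastasis model are emulated as a two-lobe
silhouette bearing small nodes. At the early stage the agent saturates the
lungs uniformly (`diffuse`); after wash-out (`localized`) the diffuse level
drops to 0.3 × and a bright rim of configurable width surrounds each node —
targeted agent bound at cluster peripheries — while the pigmented node
cores go dark. The 1/10 ex vivo dose is represented only as a lower diffuse
level; no pharmacokinetic dose model is attempted. The localization index
(rim mean over parenchyma mean, both baseline-corrected) is an invented
operationalization of "signal concentrated near the clusters": it is
scale-invariant and equals 1 exactly on a noise-free uniform lung.
Peripheral-lung signal is not separately scored (no principled mask exists
for it); it raises the lung CV only.

### What the phantom does *not* emulate

Passing recovery tests on this phantom shows the *pipeline arithmetic* is
right, not that the biology is. The phantom has no depth-dependent
attenuation (organ "depth" is folded into amplitude), no heterogeneous
autofluorescence, no motion or breathing artifacts, no partial organ
overlap (regions are disjoint by construction), and a stationary Gaussian
PSF instead of depth-varying diffusion. Real tumor SNRs depend on all of
these; the phantom's absolute SNR values (≈200 for the default tumor) are
therefore not calibrated to any published figure, and the package asserts
only ordering, plateau, separability, and invariance properties on them.

## Problem sizes used in validation

The shipped tests run the full default geometry (120 × 200 px, N = 5,
3 timepoints) for pattern checks, 20 seeded cohorts for the
recovery-bias experiment, 200 random ≤ 64 × 64 images for oracle
equivalence of the pixel statistics, and a 64 × 96 px two-region truth
where a smaller fixture suffices. These sizes keep the whole suite within
a few minutes on one CPU while leaving every statistic comfortably above
its estimation noise.

## I/O conventions

Images travel as single-plane TIFF: 16-bit integer (exact round trip;
the writer refuses to quantize silently) or 32-bit float with the scale
factor recorded in a JSON sidecar alongside subject, timepoint, view, and
filter metadata — sidecars rather than TIFF tags for portability. The
acquisition bit depth of the original station is not documented anywhere;
16-bit is a convention. Region sets are a single labeled TIFF plus a JSON
name map; a single label map makes named ROIs disjoint by construction
(annuli, which overlap everything, are derived masks and never stored in
the map). Composite overlays render the white-field in grayscale with NIR
pseudocolor above a display floor (default: the 0.95 quantile of
within-body intensity; the original display threshold is unknown) and are
purely presentational — they never feed back into quantification.
Histograms are computed on hip-normalized images for cross-image
comparability; their mean/SD ratios are invariant to that choice.

## Known limitations

* The hip-fallback autofluorescence estimate ($A = R$ times a configurable
  hip autofluorescence fraction) assumes the hip patch is free of agent
  uptake; with agents that accumulate in muscle it overestimates $A$.
* `estimateAutofluorescence` erodes the body mask (default 3 px) to avoid
  the partial-volume rim at the silhouette boundary; bodies thinner than
  twice the erosion fall back to the uneroded mask.
* The Otsu path assumes a roughly bimodal working image within the body;
  on unimodal images the threshold is unstable and the quantile method is
  the better choice.
* `mean_ratio` mode is undefined in spirit (and $\varepsilon$-guarded in
  code) when the annulus mean falls to the autofluorescence baseline.
* Overlapping anatomical regions cannot be expressed in a single label
  map; this is a representation constraint, not an oversight.
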