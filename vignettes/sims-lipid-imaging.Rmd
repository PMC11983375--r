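---
title: "Segmenting and annotating GCIB-SIMS lipid images"
author: "simsLipids maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and annotating GCIB-SIMS lipid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsLipids)
```

## The analysis problem

Gas-cluster-ion-beam secondary ion mass spectrometry (GCIB-SIMS) images
intact lipids directly from tissue sections: a focused beam of large
(CO~2~)~7k~^+^ clusters sputters material pixel by pixel, and a
time-of-flight analyzer records one negative-mode mass spectrum per
pixel. Applied to lymph-node sections, the resulting hyperspectral
images can separate malignant (diffuse large B-cell lymphoma, DLBCL)
from reactive, nonmalignant lymphoid tissue by lipid profile alone —
glycerophosphoinositols, -serines and -ethanolamines shift toward more
saturated acyl chains in the malignant tissue, and sulfatide-series
glycosphingolipids mark an aggressive, highly proliferative subtype.

`simsLipids` implements the complete analysis chain for such data:

1. **Ingestion** — imzML (continuous or processed mode) into a
   `SpectralImageCube`; mosaics of 900 µm tiles rastered at 128 × 128
   pixels (7.03125 µm per pixel, quoted as 7 µm).
2. **Peak picking** — per-image TIC-normalized mean spectra, a
   second-derivative picker producing centroids with integration
   windows, and a combined dual-range (m/z 590–800, 800–1190) table.
3. **Centroiding** — every pixel integrated over the table's windows
   into a `FeatureImage` (a `SummarizedExperiment`: centroids × pixels).
4. **Preprocessing** — per-pixel sum normalization to 1 plus square
   root; substrate removal by a k-means (k = 2) mask with zero filling.
5. **Multivariate analysis** — imaging PCA and k-means over the
   composite multi-sample image, cluster difference spectra, ion-image
   validation.
6. **Annotation** — accurate-mass assignment against a bundled lipid
   database at ±0.01 m/z, with fragment-ion hypotheses, a PS→PA rule,
   reporting-confidence levels, and ppm accuracy summaries.

A synthetic-scene generator produces mosaic images with known ground
truth so every stage is testable without instrument data.

## The peak picker

The picker operates on an averaged spectrum sampled on a uniform grid
(default 0.005 m/z):

1. Gaussian smoothing (`gaussianSigma`, default 0.02 m/z). Convolution
   edges are renormalized by the in-range kernel mass so a constant
   signal stays constant.
2. A smoothed second derivative (Savitzky–Golay, window `derivWindow`,
   default 7 samples, polynomial order 3).
3. Positive derivative values are set to zero and the remainder is
   negated, leaving one positive lobe per resolvable peak.
4. Each contiguous positive lobe becomes a centroid: the lobe-weighted
   mean m/z, a half-open integration window `[lo, hi)` spanning the
   lobe, and the apex (smoothed) intensity. Lobes carrying more than
   one interior maximum are flagged `merged` — unresolved isobaric
   pairs collapse into one centroid, which downstream interpretation
   must keep in mind.
5. Per mass range, the `nKeep` (default 300) centroids of greatest apex
   intensity are kept; ties break toward lower m/z for determinism.

The defaults were chosen once as plausible for ToF-SIMS line widths
(the smoothing scale is below the 0.05 m/z FWHM the simulator uses,
and 300 peaks per range is commensurate with the few hundred lipid
features such data carry); they are configurable and declared rather
than fitted. Peak tables are built on the grand mean of all images'
TIC-normalized spectra — averaging before picking is what makes the
table shared, which composite assembly requires.

A numerical floor (10^-12^ of the smoothed maximum) zeroes derivative
values at rounding-noise scale so featureless spectra yield no
spurious centroids. Windows are clipped at range boundaries so the
dual-range tables never overlap at the seam; a signal landing exactly
on a shared window edge belongs to the upper window (half-open
convention).

## Normalization and masking

Each pixel's centroid vector is divided by its sum and square-rooted.
The square root stabilizes the variance of counting noise, which is
why the PCA that follows is mean-centered but not variance-scaled.
All-zero pixels (no signal in any window) pass through unchanged and
are counted. Re-normalizing an already normalized image is treated as
a staging error rather than a silent no-op.

Substrate (ITO-coated glass) pixels carry roughly two orders of
magnitude less lipid signal than tissue. A two-cluster k-means over
the pixel profiles separates them; the cluster with the lower mean raw
TIC is labeled substrate — tying the label to signal level rather than
to the arbitrary cluster index. Masked pixels are zero-filled, not
dropped, so that PC1 of the subsequent PCA captures the
tissue-versus-substrate contrast exactly as a practitioner expects,
and so pixel geometry is preserved for rendering. Whether masking uses
the full profile or raw TIC alone is configurable
(`featureSpace`); the full profile is the default. Normalization
precedes masking because per-pixel normalization commutes with
zero-filling other pixels.

## PCA and k-means

Both methods run on the pixels × centroids matrix of the composite
image. PCA is computed by singular value decomposition of the
mean-centered matrix; loadings are orthonormal, explained variances
non-increasing, and component signs are normalized so each component's
largest-magnitude loading is positive (signs in PCA are arbitrary; the
reports annotate both directions). Fitting on tissue pixels only is
available (`fitTissueOnly`), with substrate pixels then scored as
zero-filled rows.

k-means uses k-means++ seeding with a fixed seed and 10 restarts,
keeping the best inertia; the initialization details are this
package's choice since common practice varies. With substrate included
and zero-filled, any adequate k yields a pure substrate cluster, so
k = 3 targets substrate/healthy/cancerous directly. A sweep mode
(k = 3…10) supports the finer within-tissue segmentation used to
isolate small sub-regions such as an apoptotic, sulfatide-rich zone.

Cluster difference spectra subtract the overall mean from each cluster
mean; size-weighted differences cancel to zero by construction, which
the tests assert. Display inversion of a cluster's trace is a
rendering flag only — stored values are never sign-flipped.

## Accurate-mass annotation

Theoretical masses come from the most-abundant-isotope element masses
(IUPAC); the deprotonated ion is the neutral monoisotopic mass minus
1.007276 Da (the proton mass — the electron stays with the anion; the
~0.5 mDa electron-mass subtlety is far below the 2-decimal reporting
precision). Sphingomyelins are observed demethylated, [M−CH~3~]^−^.
Neutral-loss fragment hypotheses subtract the loss composition from
the deprotonated-ion composition: the PS serine loss (C~3~H~5~NO~2~,
87.0320 Da), the N-acetylhexosamine−H~2~O loss (C~8~H~13~NO~5~) and
the monosaccharide loss (C~6~H~10~O~5~) seen for large
glycosphingolipids.

A search accepts every hypothesis within ±0.01 m/z of the measured
value and ranks by absolute ppm error; exact ties (a PA [M−H]^−^ is
isobaric with its PS-fragment counterpart) rank the intact ion first.
The PS→PA rule then demotes PA assignments: if a peak 87.0320 Da above
a PA assignment exists, exceeds a significance threshold (default 1%
of the base peak, configurable — "significant" is not standardized)
and itself carries an intact PS assignment, the PA assignment is
replaced by the PS fragment hypothesis and flagged. The rule changes
hypotheses, never the number of annotated peaks. Assignments below
m/z 900 carry metabolomics reporting confidence level 2; at or above
900 — where peaks may be in-source fragments of larger gangliosides —
level 2/3, with the boundary value assigned to the upper class by
declared convention.

The bundled database reproduces the species discussed in the
lymphoma-tissue application plus a few odd-chain decoys
(`prior = 0`) for testing; biological-plausibility tie-breaking is
encoded as this per-species prior flag, not inferred. Live database
queries are out of scope.

## The synthetic scene generator

The generator emulates the statistical structure of the tissue data,
not its physics. The default scene holds four members (one tile each):
healthy lymphoid tissue; DLBCL tissue; DLBCL tissue with an
aggressive, sulfatide-rich pocket; and healthy tissue with a
histiocyte pocket plus a connective strip — each tile bordered by
substrate.

Abundance profiles start from a uniform baseline over the database
species. The healthy-associated and cancer-associated contrast sets
are enriched 3:1 in their respective tissues (direction comes from the
application; the magnitude is a declared default). Sulfatide-class
species are suppressed tenfold outside the aggressive pocket and
doubled inside it, giving a >5-fold contrast by construction — its
*detection* by PCA/k-means remains a genuine pipeline test because the
detector sees only the simulated data. The histiocyte pocket applies
graded fold changes to the healthy profile (slight = 1.2×, small =
1.5×, moderate = 2×, inverses for decreases), mirroring the
intermediate cancer/healthy character such pockets show. Connective
tissue enriches sphingomyelins and a few PS/PE/PG species over
baseline — a declared stand-in, as the application characterizes this
region only qualitatively.

Each species contributes a Gaussian line at its ion m/z (flat FWHM,
default 0.05 m/z — wide enough to merge pairs split by ≤0.01, narrow
enough to resolve the PI(38:4)/PI(38:3) pair at 885.55/887.56) plus an
aggregated isotope envelope from exact binomial convolution of element
isotope distributions. This reproduces a deliberate feature of real
data: the M+2 isotopologue of PI(38:4) lands within 0.01 m/z of
PI(38:3)'s monoisotopic peak, so the two share a centroid window and
the interference survives into the feature matrix (the package does no
deisotoping, on purpose). Tissue pixels draw Poisson counts around a
mean total of 3000; substrate pixels carry a featureless baseline 100×
weaker. All randomness is fixed by the scene seed; identical
specifications give bit-identical cubes.

What the generator does **not** emulate — spatial intensity drift,
detector dead time, matrix effects, chemically structured substrate
ions, within-region biological gradients — bounds what passing tests
show: they validate the algorithms under the stated statistical model,
not instrument behavior on real tissue.

## Problem sizes and numerical choices

The worked examples and tests run the default scene at 20 × 20 pixels
per tile (1600 pixels, four members) with 150 peaks kept per range:
region recovery depends on class separation and counting statistics
per pixel, not on pixel count, so these sizes exercise the identical
code paths the full 128 × 128 geometry uses. At those sizes the
end-to-end run takes seconds; k-means recovery of
substrate/healthy/cancer reaches an adjusted Rand index above 0.9, and
a k in 3…10 isolates the aggressive pocket of its member tile.

Other declared conventions: pixel indices are 0-based, row-major,
origin top-left; composite members are packed row-wise in member order
(the visual arrangement of a figure is cosmetic); imzML is the only
on-disk spectral format, written processed-mode with 64-bit m/z and
32-bit intensities; printed m/z comparisons round half-up to 2
decimals; apex-intensity ties break toward lower m/z; degenerate
inputs (constant images, uniform masks, empty spectra) raise errors or
warnings rather than returning silently.

## Known limitations

* Annotation is putative accurate-mass assignment only (level 2/2–3);
  no MS/MS, mobility or retention evidence, no isotope-pattern
  scoring.
* The picker assumes a uniform (or near-uniform) m/z grid and a flat
  line-width model; no recalibration, no fitted lineshapes.
* PCA/k-means are spatially blind; small regions of unique chemistry
  contribute little variance and may need per-tissue re-analysis, as
  the sweep mode supports.
* The composite accepts any member count; statistical power and class
  balance are the user's responsibility.

## A minimal run

```{r pipeline, eval = FALSE}
spec <- defaultSceneSpec(rasterPx = 20L, seed = 101L)
cfg <- pipelineConfig(picker = pickerParams(nKeep = 150L))
run <- runPipeline(spec, cfg, outDir = "sims-out")
pipelineReport(run, components = 2L, topN = 5L)
```

The report lists pixel/centroid counts, mask diagnostics, variance
explained, cluster sizes, the annotated loading table of PC2 (whose
positive and negative peaks recover the injected healthy/cancer lipid
split) and the ppm accuracy summary of the annotated centroids.
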