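# simsLipids

Analysis toolkit for **GCIB-SIMS imaging lipidomics**: hyperspectral
tissue images acquired by secondary ion mass spectrometry with a gas
cluster ion beam, one negative-mode mass spectrum per pixel. The
package targets the workflow used to separate diffuse large B-cell
lymphoma (DLBCL) from nonmalignant lymphoid tissue by intact-lipid
profile, but every stage is generic MSI machinery:

* **imzML I/O** for mosaic tile images (continuous and processed
  binary modes), with tile geometry bookkeeping — a 900 µm tile
  rastered at 128 × 128 px gives the familiar 7 µm pixel.
* **Second-derivative peak picking** on averaged TIC-normalized
  spectra: Gaussian smoothing, a Savitzky–Golay second derivative,
  removal of positive features, inversion, centroid detection with
  integration windows, and top-*N* retention per mass range (default
  dual tables, *m/z* 590–800 and 800–1190, combined into one).
  Unresolved isobars collapse into a single `merged` centroid.
* **Per-pixel preprocessing**: sum-normalization to 1 and square root
  (for a pixel row *x*, the output is √(*x*/Σ*x*), so every nonzero
  pixel has unit sum of squares), then substrate removal by a k-means
  (k = 2) mask that zero-fills the low-TIC cluster.
* **Imaging PCA and k-means** over the composite multi-sample image,
  with cluster difference spectra (cluster mean − overall mean),
  loading reports and single-ion images for validation.
* **Accurate-mass lipid annotation** against a bundled database:
  [M−H]⁻ from monoisotopic mass − 1.007276 Da, [M−CH₃]⁻ for
  sphingomyelins, fragment hypotheses ([M−H−C₃H₅O₂N]⁻ for PS,
  [M−C₈H₁₃NO₅]⁻ and [M−C₆H₁₀O₅]⁻ for glycosphingolipids), a ±0.01
  *m/z* search window, ppm ranking, the PS→PA reassignment rule,
  reporting-confidence levels (2 below *m/z* 900, 2/3 above) and
  mean-|ppm| / %<5 ppm accuracy summaries.
* **A synthetic scene generator** with ground truth: mosaic images of
  healthy lymphoid, DLBCL, aggressive sulfatide-rich, histiocyte and
  connective regions on an ITO-like substrate, with exact isotope
  envelopes (including the M+2 of PI(38:4) interfering with PI(38:3)
  at Δ < 0.01) and Poisson counting noise.

The central container is `FeatureImage`, a `SummarizedExperiment`
whose assay holds centroids × pixels, with the peak table in
`rowData` and pixel geometry, sample membership and the tissue mask in
`colData`.

## Worked example

Simulate the default four-member scene (healthy, DLBCL, DLBCL with an
aggressive pocket, healthy with a histiocyte pocket) at 20 × 20 pixels
per tile and run the whole chain:

```r
library(simsLipids)
spec <- defaultSceneSpec(rasterPx = 20L, seed = 101L)
run  <- runPipeline(spec, pipelineConfig(picker = pickerParams(nKeep = 150L)))
pipelineReport(run, components = 2L, topN = 5L)
```

```
Pipeline run: 1600 pixels in 4 images, 241 centroids
Tissue pixels after masking: 1024 / 1600
PCA variance explained (top 5): 83.1% 11.6% 1.0% 0.4% 0.2%
k-means (k = 3) cluster sizes: 480 576 544
PC2 loading peaks:
   mzCenter loading     sign     lipid
1     750.5  0.2071 positive PE O-38:5
2     599.3  0.1971 positive  LPI 18:0
3     619.3  0.1912 positive  LPI 20:4
4     812.5  0.1878 positive   PS 38:3
5     857.5  0.1838 positive   PI 36:4
6     744.6 -0.1359 negative   PE 36:1
7     861.5 -0.1336 negative   PI 36:2
8     742.5 -0.1335 negative   PE 36:2
9     915.6 -0.1334 negative   PI 40:3
10    863.6 -0.1329 negative   PI 36:1
Annotation accuracy: mean |ppm| = 2.3, 84% below 5 ppm
```

Reading the output: PC1 (83%) is tissue versus zero-filled substrate;
PC2 (12%) separates the tissue classes, and its annotated loading
peaks recover the injected contrast — ether-PE, LPI, PS 38:3 and
PI 36:4 load with healthy tissue, while the more saturated PE 36:1/2,
PI 36:1/2 and PI 40:3 load with the malignant profile. The k = 3
clustering splits substrate/healthy/cancer (adjusted Rand index vs
ground truth ≥ 0.9 in the tests), and a k-means sweep of the
aggressive member isolates its sulfatide-rich pocket. The accuracy
line summarizes the ppm errors of the annotated centroids in this
simulated run.

Single quantities come from the same building blocks:

```r
pixelSizeUm(900, 128)                      # $um 7.03125, $nearestUm 7
mzIon(lipidFormula("PI", 38, 4))           # 885.5499  -> prints as 885.55
isotopeEnvelope(lipidFormula("PI", 38, 4)) # M+2 offset 2.0067, 9.3%
```

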