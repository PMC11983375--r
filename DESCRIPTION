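Package: simsLipids
Title: GCIB-SIMS Imaging Lipidomics: Peak Picking, Tissue Segmentation,
    and Accurate-Mass Lipid Annotation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for gas-cluster-ion-beam
    secondary ion mass spectrometry (GCIB-SIMS) imaging of intact lipids
    in tissue. Reads and writes imzML mosaics, builds averaged
    TIC-normalized spectra, picks and centroids peaks with a
    second-derivative algorithm, sum-normalizes and square-root transforms
    per-pixel spectra, removes conductive-substrate pixels with a k-means
    mask, segments composite multi-sample images by imaging PCA and
    k-means with cluster difference spectra, and putatively annotates
    centroids by accurate mass against a bundled lipid database with
    deprotonated-ion and fragment-ion hypotheses, a PS-to-PA fragment
    rule, reporting-confidence levels and ppm accuracy summaries. A
    synthetic-scene generator simulates mosaic lipid images with
    ground-truth region maps, isotope envelopes and Poisson counting
    noise so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    signal,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
biocViews: MassSpectrometry, ImagingMassSpectrometry, Lipidomics,
    Clustering, PrincipalComponent, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
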