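Package: histopet
Title: Linking Histological PSMA Expression to PET Uptake in Co-Registered
    Prostate Tumour Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how immunohistochemical PSMA expression, summarised
    as the H-Score of pathologist-annotated prostate cancer areas on
    whole-mount sections, relates to tracer uptake in PSMA PET. Provides
    H-Score computation and area-weighted aggregation, slab-model transfer
    of 2D section annotations into the 3D PET frame through a supplied
    transform chain, sub-voxel fractional-occupancy uptake extraction
    (SUVmean, SUVmax, in-vivo volume) without resampling the PET grid,
    threshold-surrogate gross tumour volumes with a Dice-like agreement
    statistic, automated rigid position refinement, and the nonparametric
    statistical surface (Spearman correlations with bootstrap CIs,
    Kruskal-Wallis with Dunn post-hoc comparisons, through-origin
    regression). A synthetic prostate/PET phantom generator with full
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    RNifti,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
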