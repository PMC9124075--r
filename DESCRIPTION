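Package: mfscnet
Title: Densely Connected Networks with Optimized Channel Attention for
    Histopathology Patch Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for benign/malignant and subtype classification of
    H&E-stained histopathology image patches. Implements the MFSCNet family
    of architectures: a DenseNet121 backbone augmented with an optimized
    squeeze-and-excitation channel-attention block (squeeze statistics =
    global mean, local-pooled maximum and spatial variance per channel) at
    three alternative insertion schemes (after dense blocks, after
    transition layers, or both). Also provides sparse non-negative
    matrix-factorization stain normalization in optical-density space,
    exact rotation/flip augmentation, BreakHis-style directory-tree
    manifests with stratified 7:1:2 splitting, a seeded synthetic
    H&E-patch generator built on a two-stain Beer-Lambert forward model,
    and a rank-based (Mann-Whitney, tie-corrected) AUC metric suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
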