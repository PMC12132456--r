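Package: specdex
Title: Hyperspectral Fluorescent Protein Decoding by Cosine Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes the fluorescent-protein (FP) identity of single cells
    from 100-channel hyperspectral microscopy images. Four sequential
    excitation blocks are concatenated into one spectrum per cell, and each
    cell is assigned the reference FP with which its spectrum has the
    maximum cosine similarity. Includes per-cell spectrum extraction from
    label masks, reference-library construction with dim-FP detection via
    Wasserstein-distance clustering, monoculture error-rate and FP-minus-one
    false-positive statistics, combinatorial selection of spectrally
    resolvable FP palettes, an analytic and Monte-Carlo model of spatial
    clone misclassification, paint-by-number rendering of decoded images,
    and a ground-truthed synthetic hyperspectral scene simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
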