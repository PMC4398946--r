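Package: audtopo
Title: Topographic Mapping of Amplitude-Modulation Rate and Frequency in
    Auditory Cortex from Sparse-Design fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mapping the cortical topography of two
    fundamental sound dimensions, spectral frequency (tonotopy) and
    amplitude-modulation rate (periodotopy), from sparse temporal-sampling
    BOLD time series. Provides a synthetic-data generator that emulates
    sparse auditory fMRI acquisitions and continuous phase-encoded runs over
    an idealised cortical sheet carrying concentric iso-rate bands and
    per-field tonotopic gradients with reversals; a voxel-wise general linear
    model with discrete-cosine drift regressors and global scaling; contrast
    and best-condition feature maps; sphere-based volume-to-surface
    projection; per-field two-dimensional gradient regression with
    relative-angle statistics and table-style aggregation; and a
    cross-correlation phase-encoded analysis that assigns preferred
    frequencies from the lag between opposite stimulus progressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    signal,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
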