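Package: dwtgabor
Title: Hybrid Wavelet-Gabor Texture Features for Biomedical Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Texture-based computer-aided classification of biomedical images
    as normal versus abnormal. Extracts the diagonal detail (HH) subband of a
    two-dimensional Daubechies-4 discrete wavelet transform, filters it with a
    bank of twelve real Gabor kernels (four orientations by three central
    frequencies), summarises each response by the entropy and uniformity of
    its coefficient histogram, and classifies the resulting feature vectors
    with a degree-2 polynomial-kernel support vector machine under tenfold or
    leave-one-out cross-validation. Wavelet-only and Gabor-only feature
    baselines, a seeded synthetic image generator for end-to-end testing, and
    an experiment driver producing per-fold performance tables are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
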