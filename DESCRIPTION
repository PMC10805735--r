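Package: nucleoprofile
Title: Boundary-Normalized Radial Profiling of Nucleolar Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how a fluorescent signal distributes relative to
    core-shell nuclear condensates (nucleoli). Provides a synthetic
    multi-channel microscopy image generator with analytic ground truth,
    threshold-based nuclear and nucleolar segmentation, boundary-normalized
    radial intensity profiling (normalized distance d with d = 1 at the
    condensate outline), inside/outside window statistics, nonparametric
    group comparisons (Mann-Whitney U and Steel-Dwass all-pairs tests
    implemented from scratch with exact and asymptotic variants), and
    helpers for gel-based crosslink-fraction and ChIP-qPCR percent-input
    quantification, tied together by a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
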