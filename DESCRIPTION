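Package: ssmri
Title: Self-Supervised MRI Reconstruction via Variable-Density Noisier2Noise and SSDU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for training image-reconstruction networks on sub-sampled
    multi-coil MRI k-space without fully sampled reference data. Implements
    variable-density sampling mask construction, the diagonal K-matrix
    correction that de-biases Noisier2Noise-style training under
    non-uniform sampling, the SSDU loss masking and its K-weighted variant,
    a compact unrolled data-consistency estimator, a self-supervised
    training loop with per-epoch re-drawing of the partitioning mask, and
    exact enumeration oracles that verify the conditional-expectation
    identities underlying the framework on small discrete ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
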