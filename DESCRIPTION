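Package: mriseqid
Title: MRI Sequence Type Identification from DICOM Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies the pulse-sequence type of MRI scans (3D T1, 2D
    FLAIR, PD/T2, T2-star, DTI, fMRI, localizer-type "junk", and more)
    from DICOM header metadata alone, without reading pixel data.
    Extracts an 18-feature metadata record per series (sequence-specific
    tags, timing parameters, geometry, vendor-specific diffusion
    b-values), engineers the features with explicit missing/empty
    sentinels and one-hot encoding, and trains a random-forest
    classifier whose per-scan prediction confidence flags scans of
    sequence types unknown to the model. Includes a synthetic metadata
    generator emulating multi-site heterogeneity (overlapping repetition
    time ranges, many missing sequence names, vendor dialects, many
    sequence-name variants) and the full evaluation protocol: learning
    curves under disproportionate stratified sampling, confidence
    distributions, unknown-class and leave-one-class-out experiments,
    and aggregated feature importance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
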