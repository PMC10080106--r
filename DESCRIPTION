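Package: cytoscreen
Title: Spectral Flow Cytometry Immunophenotyping and Drug-Screen Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectral flow-cytometry immunophenotyping of peripheral
    blood mononuclear cells (PBMCs): fluorophore spectral signatures with
    similarity and complexity indices, reference-control signature estimation
    and per-event least-squares unmixing, antibody titration stain indices,
    declarative hierarchical gating with automatic 1-D threshold placement,
    subset frequency and median-fluorescence (MFI) extraction, and the
    downstream screening statistics used in drug and patient studies:
    fractional differences versus vehicle control, outlier masking, column
    clustering, one- and two-sample t tests with star annotation, min-max
    normalization, variance filtering, principal-component embedding and a
    silhouette separation score. A seeded synthetic-data generator emulates
    hierarchical PBMC composition, log-normal marker expression, donor
    variability, stimulation and drug effects, titration ladders and raw
    multi-detector spectra, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
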