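Package: imeqc
Title: Recording-Quality and Tissue-Response Analytics for Chronic
    Intracortical Microelectrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic intracortical microelectrode (IME)
    studies: seeded synthetic-data generators for multichannel extracellular
    recordings, implant-site fluorescence images and dialysis release assays;
    common-median referencing, band-pass filtering, -4 sigma spike detection
    and amplitude/motion artifact screening; silhouette-selected k-means spike
    sorting with rule-based unit verification; per-unit recording-quality
    metrics (peak-to-peak voltage, noise RMS, SNR, spike rate) with a
    putative-unit filter and ROUT outlier removal; active-electrode-yield
    statistics with two-sided proportion z-tests; concentric-ring
    quantification of fluorescence intensity and neuron density around an
    implant hole; and encapsulation-efficiency and replacement-corrected
    cumulative dialysis release calculations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    cluster,
    jsonlite,
    stats,
    utils,
    tools,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
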