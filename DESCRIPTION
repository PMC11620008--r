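Package: onhmark
Title: Device-Agnostic Optic Nerve Head Biomarkers from Segmented OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts optic nerve head (ONH) morphometry from multi-class
    segmentation masks of OCT volumes, independent of the acquiring device:
    Bruch's membrane opening (BMO) area by direct least-squares ellipse
    fitting of the en-face BM boundary, circumpapillary retinal nerve fiber
    layer (cpRNFL) thickness profiles with TSNIT sector and clock-hour means,
    BMO minimum rim width (MRW) from radial scans (acquired or synthesized
    from cube acquisitions), and cup volume from per-B-scan BM-endpoint
    chords. Includes the agreement statistics used to compare devices (Dice
    coefficient, two-way absolute-agreement single-measure intraclass
    correlation with F-based confidence intervals, absolute-difference
    summaries, circular profile smoothing) and a synthetic ONH phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    EBImage,
    RNifti,
    tiff,
    png,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
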