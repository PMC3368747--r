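Package: orthospect
Title: Standardised Volumetric Analysis of Orthopaedic SPECT/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative 3D analysis of co-registered SPECT/CT volumes for
    orthopaedics. Constructs femoral and tibial anatomical reference frames
    from landmarks (mechanical axis, transepicondylar axis), normalises SPECT
    tracer intensities against a clinically neutral reference region in the
    femoral shaft, segments altered-uptake hotspots by thresholding, and
    reports volumetric hotspot metrics (volume, normalised max/mean intensity,
    centroid in anatomic coordinates, Welch t-statistic against the reference
    distribution). Includes isosurface mesh extraction for bone and hotspot
    surfaces, readers/writers for DICOM series, NIfTI and NRRD volumes, a
    synthetic knee phantom generator with ground truth for validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
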