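Package: reoct
Title: Resolution-Enhanced Optical Coherence Tomography by Coherent
    Averaging and Computational Bandwidth Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolution-enhanced optical coherence tomography
    (RE-OCT): coherent-average noise suppression of stacks of complex
    en face field images followed by computational transverse
    spatial-frequency bandwidth expansion (magnitude-based
    deconvolution).  Includes the accompanying metrology (noise
    intensity, spatial-frequency dynamic range, phase-correlation
    limit, radial Gaussian point-spread-function fits for resolution
    and signal-to-background ratio, resolution-enhancement
    efficiency), inter-frame bulk-shift and global-phase registration,
    an information-capacity utility, and a synthetic coherent-imaging
    phantom generator with paired noise images for end-to-end
    validation without instrument data.  Stacks are stored in HDF5
    with paired real and imaginary planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    rhdf5,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
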