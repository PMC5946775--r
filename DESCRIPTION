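Package: visoct
Title: White-Light Polarization-Sensitive Spectral-Domain OCT Processing and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for visible-light (400-700 nm)
    polarization-sensitive spectral-domain optical coherence tomography:
    dual-channel spectral reconstruction (background subtraction, channel
    alignment, k-space resampling, Fourier transform), multi-band numerical
    dispersion compensation with automatic coefficient search, phase
    retardation imaging with SNR masking and error propagation,
    spectroscopic true-colour RGB composition, en-face projections and
    lesion height mapping, and system characterization (PSF width,
    sensitivity, roll-off).  A physics-based simulator generates
    dual-channel spectral interferograms from layered retinal phantoms so
    that every processing stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    signal,
    jsonlite,
    rhdf5,
    tiff,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
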