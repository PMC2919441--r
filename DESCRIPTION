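Package: relaxmap
Title: Pixel-Wise T1, T2 and T2* Relaxation-Time Mapping from Magnitude MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates quantitative T1, T2 and T2* relaxation-time maps from
    multi-image magnetic-resonance source series (classic inversion recovery,
    Look-Locker, MOLLI, single- and multi-echo decay) by per-pixel
    Levenberg-Marquardt curve fitting. Restores the signal polarity lost by
    magnitude reconstruction of inversion-recovery data through a cyclic
    sign search, applies the Look-Locker apparent-T1 correction, gates
    background pixels by a noise threshold, supports rigid integer-pixel
    registration shifts, reads and writes uncompressed DICOM series, and
    ships a synthetic multi-compartment gel-phantom simulator with Rician
    noise for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
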