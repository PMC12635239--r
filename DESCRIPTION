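Package: pulsecloak
Title: Reversible Concealment of Remote Photoplethysmography Signals in
    Facial Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for privacy-preserving transmission of facial video.
    Conceals the cardiac signal readable by remote photoplethysmography
    (rPPG) through frame-wise sinusoidal modulation of the green channel
    inside facial regions, driven by a fake-heartbeat frequency schedule
    derived from, and transmitted under, RSA encryption. Because the
    modulation is an integer increment applied to losslessly stored
    frames, the receiver restores the original video bit-exactly.
    Includes eight classical rPPG extraction methods, Butterworth
    band-pass filtering, Welch-style spectral heart-rate estimation, and
    an evaluation suite (PSNR, SSIM, dynamic time warping, Pearson
    correlation, heart-rate error, and a composite overall score), plus a
    deterministic synthetic pulsatile-face video generator so the whole
    pipeline can be exercised without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    openssl,
    png,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
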