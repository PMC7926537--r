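Package: manucount
Title: Calibration-Free Magnetic Counting of Hand Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Counts hand (wrist and finger) movements from a wrist-worn
    array of four magnetometers sensing a finger-worn permanent-magnet
    ring.  Implements the differential reading that cancels the Earth's
    field, the HAND (Hand Activity estimated by Nonlinear Detection)
    run-length counting algorithm with its device-noise calibration, a
    conventional wrist-accelerometry activity counter for comparison,
    and a dipole-physics simulator of the robotic wrist/finger testbed
    and in-lab exercise protocols used to characterise the algorithm,
    so the whole pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
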