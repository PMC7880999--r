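Package: parmoco
Title: Motion-Compensated CT Reconstruction from Conjugate Partial-Angle Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and correction of motion artifacts in non-gated axial
    lung CT. Provides an analytic moving-phantom simulator (fan-beam line
    integrals with per-view motion), fan-to-parallel rebinning, filtered
    backprojection (full and half scan), conjugate partial-angle
    reconstruction (PAR) pairs, band-pass filtering, B-spline free-form
    deformation registration between the two PARs, linear-in-time motion
    vector field interpolation, motion-compensated filtered backprojection,
    and artifact quantification by Parzen-window kernel-density entropy and
    normalized positivity with automatically chosen thresholds, plus paired
    statistics for phantom experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
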