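Package: rotob1
Title: Rotating Radiofrequency-Coil B1 Encoding and Image Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and algebraic reconstruction for silent,
    gradient-coil-free magnetic resonance imaging in which a single
    transmit coil with a spatially nonuniform B1+ field is mechanically
    rotated about the sample and the flip angle is modulated from one
    phase encode to the next.  Provides digital phantoms, shaped
    radiofrequency pulse envelopes and their flip-angle-modulation
    schedules, rotatable complex coil sensitivity maps with
    acquisition-noise injection, an unconditionally stable midpoint
    finite-difference Bloch solver, pseudo k-space simulation,
    encoding-matrix assembly, reconstruction by truncated-SVD
    pseudo-inverse or LSQR with percentage-deviation metrics, and
    end-to-end experiment pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
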