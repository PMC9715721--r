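Package: photonbp
Title: Stochastic Photonic Backpropagation for Three-Layer Logistic Networks
Version: 0.1.0
Authors@R: person("photonbp", "maintainers", email = "photonbp@example.org",
    role = c("aut", "cre"))
Description: Online training of a three-layer logistic network with
    biophoton-inspired learning rules: standard backpropagation, stochastic
    q-masked gradient updates, one-bit (sign) updates of fixed magnitude, and
    sign updates corrupted by uncorrelated plus/minus noise. Includes readers
    for IDX-format digit data, seeded synthetic dataset generators (Gaussian
    class blobs and low-resolution noisy digit glyphs), an online training
    loop with moving-average error tracking and periodic validation, grid
    sweep runners over the masking proportion and learning rate, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
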