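Package: fcgrad
Title: Resting-State Functional Connectivity and Cortical Gradient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for parcellated resting-state fMRI analysis:
    scan-level denoising (Friston-24 motion expansion, component-based
    physiological noise proxies, motion-spike scrubbing, zero-phase band-pass
    filtering), Fisher-z functional connectivity metrics (parcel matrices,
    network seed maps, within- and between-network connectivity, global
    connectivity), cortical gradients via diffusion map embedding with
    Procrustes alignment to a group template, within- and between-network
    gradient dispersion, pre/post-by-group statistical contrasts with
    Benjamini-Hochberg correction, and ordinary-least-squares brain-behavior
    association models. Includes a synthetic cohort generator that plants
    block-structured covariance, group-by-time effects, motion traces, and
    gradient geometry, so every stage of the pipeline is verifiable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
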