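Package: kmmae
Title: Koopman Multi-Modal Auto-Encoders for Shared Linear Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a single shared linear latent dynamics that explains several
    nonlinear modality observations of one dynamical system, using a multi-modal
    auto-encoder whose joint hidden layer evolves under a finite approximation of
    the Koopman operator.  Supports time-delay (Hankel) embedding with data-driven
    selection of the embedding dimension (false nearest neighbours) and delay
    (first minimum of mutual information), denoising and missing-modality training
    via sentinel masking, reconstruction and multi-step prediction through the
    linear propagator, restoration of masked modalities from the remaining ones,
    and detection of dynamics-change events (reaction times) from spikes in the
    reconstruction and prediction losses.  Includes a synthetic multi-modal data
    generator with known ground-truth latent dynamics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
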