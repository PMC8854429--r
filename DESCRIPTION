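Package: tractsa
Title: Tract-Specific Anisotropy from Probabilistic Tractography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the single most probable white-matter trajectory
    between two grey-matter regions of interest from probabilistic
    tractography visitation maps, computes per-participant anisotropy
    specific to that trajectory by regressing the diffusion-weighted
    signal on a tract-orientation regressor, and tests covariate effects
    along the trajectory with one-dimensional random-field cluster
    statistics. Includes a synthetic phantom generator with known ground
    truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
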