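Package: somatomap
Title: Dynamic Neural Field Model of Somatotopic Map Formation and
    Reorganization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the formation, maintenance and lesion-induced
    reorganization of ordered topographic maps in primary somatosensory
    cortex (area 3b). A patch of skin carrying Merkel-ending
    mechanoreceptors feeds a two-dimensional dynamic neural field with
    difference-of-Gaussians lateral connectivity; spatially localized
    activity bumps drive plasticity of the feed-forward thalamocortical
    weights through a lateral-excitation-gated Oja-style rule. Includes
    typed skin and cortical lesion masks (border-preserving, splitting,
    and hole-punching geometries), receptive-field analysis (centers of
    mass, normalized sizes, size histograms, response-map mosaics,
    topographic-order diagnostics) and reproducible experiment
    protocols for training, retraining after lesions, and verifying the
    field's input-matching property.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
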