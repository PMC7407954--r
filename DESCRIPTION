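Package: chcq
Title: Cortico-Hippocampal Qubit-Neuron Networks for Classical Conditioning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates classical-conditioning experiments with a
    cortico-hippocampal computational quantum (CHCQ) model built from two
    coupled phase-encoded qubit-neuron networks: a hippocampal autoencoder
    trained by instar and outstar rules, and a cortical single-output
    network trained by instar and Widrow-Hoff (LMS) rules. Provides the
    full task battery of standard conditioning paradigms (acquisition,
    extinction, stimulus discrimination, discrimination reversal, blocking,
    overshadowing, easy-hard transfer, latent inhibition, sensory and
    compound preconditioning, context shifts), trials-to-criterion
    measurement, intact versus hippocampal-lesioned systems, a generic
    feedforward baseline, and a calibration grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
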