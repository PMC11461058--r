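Package: artefactHMM
Title: Categorical Hidden Markov Models of Artefact Evolution and Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models artefacts as categorical hidden Markov models whose hidden
    states are material shapes and whose observations are the functions those
    shapes afford. Provides exact forward filtering and multi-step state
    forecasting, seeded trajectory simulation from a generative process,
    entropy-based environmental precision of likelihood and transition
    matrices, covert-attention gain control by temperature scaling of
    likelihood columns, count-based learning of model parameters from
    tabulated artefact records, expected-information-gain salience for
    epistemic action selection in a perception-action loop, and a synthetic
    archaeological record generator with configurable missingness and
    precision degradation. Includes bundled visual-foraging and knapping-tool
    configurations and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'artefactHMM-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'model-core.R'
    'precision.R'
    'learning.R'
    'salience.R'
    'synthetic-record.R'
    'io.R'
    'bundled-configs.R'
    'cli.R'
RoxygenNote: 7.3.3
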