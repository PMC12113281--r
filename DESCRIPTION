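Package: hborient
Title: Head-Body Orientation Integration Analysis for Primate STS Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single- and multi-unit spiking data from
    experiments that independently manipulate the head and body orientation of
    a monkey avatar: firing-rate extraction and three-stage responsiveness and
    selectivity screening, monkey-sum index, head-by-body interaction ANOVA
    with additive-model residuals, split-half reliability with Spearman-Brown
    correction, orientation-balanced pseudo-population decoding of head-body
    configuration angle with linear support vector machines and permutation
    null distributions (including cross-centering, cross-orientation,
    sum-versus-configuration and upright-versus-inverted contrasts, and
    neuron-dropping), and mirror-symmetry correlation-distance analysis of
    marginal orientation tuning. Includes a synthetic population generator
    with controllable additive and conjunctive von Mises tuning so the whole
    chain can be exercised and calibrated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
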