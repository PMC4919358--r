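Package: randpam
Title: Random Photon Absorption Modelling for Microvillar Photoreceptors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic modelling of photon sampling by the microvillus
    population of a fly photoreceptor. A fixed per-time-bin photon count is
    distributed over tens of thousands of independent sampling units
    (microvilli), either by exact multinomial allocation or by a
    compound-binomial drawing scheme, under strict per-bin photon
    conservation. Closed-form hit statistics (binomial and Poisson photon-hit
    distributions, multi-photon-hit percentages, activated-microvilli
    fractions) quantify how often two or more photons land on the same
    microvillus in one time bin. A gain-control layer computes the normalized
    input-output gain, its analytic bounds under linear and no-summation
    quantum-bump production, and the quantum-gain factor for arbitrary
    sublinear bump-charge models. Stimulus generators produce constant,
    band-limited Gaussian white-noise and 1/f naturalistic photon-count time
    series at millisecond resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
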