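Package: admixQTL
Title: QTL Mapping Power and False-Positive Control in Simulated Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of multi-breed admixed livestock-style
    populations (burn-in, breed divergence, half-sib expansion, crossing, and
    admixture) together with the association-mapping toolkit needed to compare
    genome-wide QTL mapping strategies on the simulated data: single-marker
    regression with and without breed composition, pedigree-based mixed linear
    models fitted by eigendecomposition REML, and a BayesCpi Bayesian
    multiple-regression Gibbs sampler reporting posterior inclusion
    probabilities. Empirical significance thresholds are derived from null
    chromosomes or from a sliding-window effective-number-of-tests estimator,
    and detections are scored into power, false-positive rate, accuracy and
    positive predictive value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
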