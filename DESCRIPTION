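Package: diashrink
Title: Shrinkage-Based Differential Abundance Testing for DIA-MS Fragment Data
Version: 0.1.0
Authors@R:
    person("diashrink", "developers", email = "diashrink@example.org",
           role = c("aut", "cre"))
Description: Peptide-level differential abundance testing for quantitative
    bottom-up proteomics with data-independent acquisition mass spectrometry
    (DIA-MS). Implements a feature-based shrinkage t test that models the
    structured covariance of log-transformed fragment ion quantities
    (within-replicate fragment correlations induced by ionization
    efficiencies, cross-replicate covariance induced by the data acquisition
    rate) using James-Stein-type shrinkage of correlations and variances, with
    bootstrap estimation of the degrees-of-freedom. Also provides a
    hierarchical generative simulator of fragment-level quantification
    reports (log-normal peptide quantities, beta acquisition rates,
    cross-condition-correlated Dirichlet ionization efficiencies), classical
    paired and Welch t baselines, dose-response p-value combination, local
    false discovery rate scoring with protein-level aggregation, and a
    simulation benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
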