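Package: gmmnea
Title: Bandwidth-Free Reconstruction of Nuclear-Ensemble Absorption Spectra
Version: 0.1.0
Authors@R:
    person("gmmnea", "maintainers", email = "gmmnea@example.org", role = c("aut", "cre"))
Description: Reconstructs electronic absorption cross-section spectra from
    nuclear-ensemble quantum-chemistry outputs (per-geometry vertical
    excitation energies and oscillator strengths). Implements the classic
    discrete nuclear-ensemble approach with Gaussian phenomenological
    broadening, a data-driven weighted-KDE bandwidth selector (auto-delta),
    and a bandwidth-free closed-form spectrum built from per-band bivariate
    Gaussian mixture models selected by BIC (GMM-NEA), with percentile
    bootstrap confidence bands for both routes. Also provides robust
    Mahalanobis outlier screening of quantum-chemistry points with false
    discovery rate control, relative-integral-change convergence metrics for
    active learning, photolysis-rate integration against actinic-flux tables,
    a synthetic-ensemble generator for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
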