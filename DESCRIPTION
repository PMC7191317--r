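Package: apsens
Title: Gaussian Process Emulation and Sensitivity Analysis of Human Atrial
    Action Potential Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the Courtemanche and Maleckar models of the human
    atrial myocyte under S1 and S1-S2 pacing, extracts action-potential and
    calcium-transient biomarkers, and performs a two-stage variance-based
    sensitivity and uncertainty analysis through Gaussian process emulators
    with a linear mean and squared-exponential covariance. Provides Latin
    hypercube experimental designs over normalized parameter spaces,
    weak-prior marginal-likelihood emulator training with restarts, closed
    form first-order and total-effect Sobol indices under independent
    Gaussian input measures, main-effect curves with sign assignment,
    standardized multivariate regression indices, uncertainty propagation,
    and APD restitution surfaces, together with a fast closed-form toy
    action-potential generator so the full pipeline is testable in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
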