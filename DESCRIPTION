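Package: gestaflux
Title: Longitudinal Maternal Serum Cytokine Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of longitudinal maternal serum cytokine
    panels across gestation. Provides a synthetic multi-cohort study generator
    (trajectory templates, covariate effects, multiplex assay forward model
    with lot and plate artifacts, late-term labor outcomes with competing
    events), assay preprocessing (bridge-sample inter-lot and anchor-based
    intra-lot fluorescence correction, 5PL calibration with power-variance
    limits of detection and quantification, left-censored lognormal EM
    imputation, panel exclusion rules, cohort accounting), penalized-spline
    mixed-model trajectories with a subsampling robustness screen, repeated
    measures ASCA+ multivariate decomposition with jackknife validation, and
    late-term analyses (Mann-Whitney comparisons, Fine-Gray subdistribution
    hazards, O-PLS-DA classification with permutation testing, covariate
    regressions on birth-weight z-scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    MASS,
    minpack.lm,
    mgcv,
    lme4,
    cmprsk,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
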