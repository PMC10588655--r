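Package: qboldr
Title: Quantitative BOLD and Arterial Spin Labeling Modeling of Brain
    Oxygenation and Perfusion
Version: 0.1.0
Authors@R:
    person("qboldr", "developers", email = "qboldr@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping brain oxygen extraction fraction (OEF) and
    deoxygenated blood volume (DBV) from asymmetric spin echo (ASE) MRI with
    the two-compartment quantitative BOLD (qBOLD) signal model, for
    quantifying cerebral blood flow (CBF) and arterial transit time from
    multi-delay pseudo-continuous arterial spin labeling (pcASL) with the
    general kinetic model, and for combining both into the cerebral metabolic
    rate of oxygen (CMRO2). Includes voxelwise maximum-a-posteriori fitting
    with Gaussian priors, physiological exclusion and group-map rules, a
    digital phantom generator for paired physiological conditions
    (pre/post vasodilation), region-of-interest statistics with paired tests
    and Bonferroni correction, and linear mixed-effects association between
    oxygenation and perfusion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
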