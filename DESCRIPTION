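Package: t1dsim
Title: Hybrid Agent-Based Simulation of Type 1 Diabetes Progression in the NOD Mouse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid in-silico model of type 1 diabetes (T1D) progression in the
    non-obese diabetic (NOD) mouse. A spatial agent-based simulator couples
    pancreatic islets, circulation, and pancreatic lymph nodes (PLNs): apoptotic
    beta cells release autoantigens, dendritic cells engulf them and migrate to
    the PLNs as antigen-presenting cells, naive CD8+ T cells are activated,
    differentiate, and infiltrate islets as cytotoxic T lymphocytes that destroy
    beta cells. Two closed-form kinetic submodels drive dendritic-cell
    recruitment (mass-action) and beta-cell quiescence shortening (a power law in
    the apoptotic fraction). The analysis stack includes Latin hypercube
    calibration against weekly infiltrating-CD8 counts, one-at-a-time local
    sensitivity screening with one-way ANOVA, extended Fourier amplitude
    sensitivity testing (eFAST) of disease-onset time, and therapy-directed
    simulation campaigns over intervention type, administration week, and dose.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
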