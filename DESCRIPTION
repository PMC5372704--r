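Package: oenoflux
Title: Constraint-Based Metabolic Modeling of Heterofermentative Lactic Acid Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and interrogating small genome-scale metabolic
    models of heterofermentative lactic acid bacteria such as Oenococcus oeni:
    flux balance analysis with reduced-cost extraction on a built-in
    bounded-variable simplex solver, flux variability analysis with blocked
    reaction and dead-end metabolite detection, in silico medium construction
    with nutrient-omission, carbon-source and gene/reaction deletion screens
    validated through confusion-matrix statistics, grid-sweep estimation of
    non-growth-associated maintenance (NGAM) ATP from measured exchange rates,
    scaled reduced-cost sensitivity analysis of exchange fluxes, and
    hit-and-run Monte Carlo sampling of the steady-state flux polytope. Ships
    a configurable generator for a miniature phosphoketolase-pathway network
    (D-lactate/acetate/ethanol fermentation, mannitol and erythritol redox
    branches, proton-consuming malolactic decarboxylation coupled to ATP
    synthase) with recorded ground truth for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
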