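Package: tracefate
Title: Positional 13C Label Propagation and Isotopologue Analysis for
    Central Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing and interpreting 13C stable-isotope tracing
    experiments in central carbon metabolism. Simulates positional carbon
    labeling through configurable atom-transition networks (glycolysis,
    oxidative, reductive and bifurcated TCA variants, and a pentose phosphate
    shunt) with explicit CO2-pool bookkeeping and bicarbonate recycling,
    collapses isotopomer distributions to mass-isotopologue distributions
    (MIDs), corrects MIDs for natural 13C abundance, quantifies metabolite
    abundances from GC-MS ion-fragment integrals against an internal standard
    via molar relative response factors, scores candidate TCA architectures
    against diagnostic isotopologue profiles, computes per-glucose ATP and
    cytosolic redox budgets for alternative metabolic strategies, and
    generates synthetic data sets with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
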