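Package: octmufr
Title: Computational Fractional Flow Reserve from Angiography and
    Coregistered Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast one-dimensional computation of a fractional-flow-reserve
    (FFR) surrogate for coronary vessels.  Implements the single-projection
    Murray-law quantitative flow ratio (muQFR) from an angiographic lumen
    profile, and its OCT-modulated variant (OCT-muFR) in which the segment
    covered by an optical coherence tomography pullback replaces the
    angiographic lumen after landmark-based coregistration.  Reference
    (non-diseased) vessel diameter is reconstructed with Murray-law
    step-downs across bifurcations; patient-specific hyperemic flow is
    estimated from the TIMI frame count; pressure loss combines Poiseuille
    viscous friction with Borda-Carnot separation losses at stenosis exits.
    Includes the diagnostic-evaluation statistics used to validate such
    methods against wire-based FFR (exact binomial confusion metrics,
    DeLong AUC comparison, Bland-Altman agreement, absolute-agreement ICC,
    dependent-correlation tests) and a seeded synthetic vessel generator
    with a fine-grid ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
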