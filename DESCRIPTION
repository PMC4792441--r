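Package: oemri
Title: Oxygen-Enhanced MRI Analysis of Lung Density and Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of oxygen-enhanced magnetic resonance
    imaging (OE-MRI) of the lung. Generates digital phantoms and two-gas-state
    (air / 100% oxygen) inversion-recovery magnitude image series, performs
    pixel-wise three-parameter relaxometry to map the longitudinal relaxation
    rate R1 and the signal at full relaxation S0, derives oxygen-uptake (delta
    R1) and oxygen-delivery (delta R2*) maps, and provides whole-lung ROI
    statistics, equal-count density-bin analysis, an animal-level permutation
    test and an animal bootstrap for binned group contrasts, as used to
    characterise elastase-induced emphysema in the mouse.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
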