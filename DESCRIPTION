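Package: solubilome
Title: Proteome Solubility Profiling and Cytoplasm Biophysics During Spore Germination
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sedimentation-fractionation solubility proteomics and
    spore-cytoplasm biophysics. Computes the pellet-partition index (P_index)
    from supernatant/pellet abundance tables with detection filtering, clusters
    time-course solubility trajectories into canonical classes, performs
    hypergeometric annotation enrichment against a detected-protein background,
    and quantifies phosphopeptide relative-abundance trajectories. A companion
    biophysics layer provides single-particle tracking (detection, linking,
    mean squared displacement, diffusion estimation), ratiometric pH-biosensor
    calibration and inversion, growth-curve heat-resistance scoring,
    fluorescence heterogeneity, and trehalose quantification. A synthetic-data
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
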