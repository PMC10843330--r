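Package: kvrecoil
Title: Rheological Analysis of Laser-Ablation Recoil in Epithelial Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting laser-ablation experiments in developing
    epithelia such as the Drosophila pupal wing. Fits post-ablation membrane
    recoil with a double Kelvin-Voigt viscoelastic model (fast and slow
    relaxation modes), extracts displacement traces from space-time kymographs
    by sub-pixel membrane ridge tracking, quantifies the cell-elongation
    nematic tensor on segmented cell polygons with peak-based time alignment,
    performs a coarse decomposition of tissue shear into cell-shape change and
    rearrangements, and provides genotype-comparison statistics including a
    subsample-with-replacement Kruskal-Wallis power analysis. Seeded synthetic
    generators emulate every input so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
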