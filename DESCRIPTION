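Package: centrofish
Title: Quantification of Centrosomal mRNA Localization and Local Translation in 3D smFISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify messenger RNA enrichment and local translation around
    centrosomes in three-dimensional single-molecule FISH / immunofluorescence image
    stacks. Provides sub-voxel spot detection (scale-matched Laplacian-of-Gaussian),
    pericentriolar-material segmentation with intensity-weighted centers of mass,
    nearest-centrosome radial distribution profiles in fixed 0.5 micron bins,
    nascent-chain translation-site calling from N- versus C-terminus epitope signals,
    per-cell centrosomal intensity and mRNA-count statistics with Welch or Student
    t-tests, and a ground-truthed synthetic 3D microscopy image generator (anisotropic
    Gaussian PSF, Poisson shot noise plus Gaussian read noise) with condition presets
    for translation-inhibitor and cell-cycle experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
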