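Package: smtmsim
Title: Single-Molecule Tracking and Multifocal Structured Illumination
    Analysis of Nuclear Factor Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse how nuclear factors explore chromatin by
    combining single-molecule tracking (SMT) with multifocal structured
    illumination microscopy (mSIM) of DNA density. Provides a synthetic-data
    generator (nuclear density phantoms, three-state diffusion trajectories
    with axial escape, multifocal excitation frame stacks), mSIM image
    reconstruction by virtual pinholing and pixel reassignment, LoG spot
    detection and LAP track linking, displacement-distribution kinetic
    modelling with axial-escape correction and BIC model selection, a
    diffusion-state hidden Markov model for track segmentation,
    diffusional-anisotropy (fold-anisotropy) statistics, and mapping of
    classified single molecules onto normalized DNA-density maps (quartile
    enrichment, instantaneous-diffusion heatmaps, radial density profiles,
    bound/diffusing pair cross-correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    igraph,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
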