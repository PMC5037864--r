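Package: qdepth
Title: Penetration Depth of Nanoparticles in Epithelial Monolayers from 3D
    Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how deep fluorescently labelled nanoparticles
    penetrate past the apical membrane of an epithelial cell monolayer in
    two-channel 3D confocal/two-photon stacks. Implements the full analysis
    chain: optional Richardson-Lucy maximum-likelihood deconvolution,
    channel-specific lateral Gaussian smoothing, axial-shift membrane
    thinning, Otsu thresholding, 26-connected object labelling,
    marker-based watershed splitting of small agglomerates, volume and
    intensity object filters, signed axial distances from particle centres
    of mass to the extracted apical membrane surface, and a Gaussian fit to
    the pooled distance histogram whose peak position is the penetration
    depth statistic. A synthetic scene generator renders monolayer stacks
    with exact ground truth (membrane sheet, PSF-shaped particle spots,
    agglomerates, organelle spheres, Poisson and Gaussian noise) so every
    stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
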