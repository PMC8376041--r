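Package: GradQuant
Title: Quantification of Anterior-Posterior Morphogen Gradients in Early
    Drosophila Embryos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying anterior-posterior (AP) morphogen
    gradients, such as bicoid mRNA and Staufen protein, in sagittal
    sections of early Drosophila embryos. Intensity profiles are
    extracted from grayscale images via chains of circular regions of
    interest along apical and basal cortical contours, decomposed into
    one-, two- or three-exponential models by bounded multi-start
    nonlinear least squares, and summarised into staging features
    (anterior exponential base per layer, apical:basal log intensity
    ratio, shallow-component ratio). Embryos are classified into the
    pre-blastoderm, syncytial-blastoderm and cellularization stages by
    linear discriminant analysis, with permutation tests for group
    differences and nine-subgroup developmental trajectories. Images are
    further decomposed by 2D and shaped-2D singular spectrum analysis
    (Hankel-block-Hankel embedding, SVD, diagonal averaging) into trend,
    mid-frequency and noise components. A seeded synthetic-embryo
    generator with full ground truth supports validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    MASS,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Visualization, CellBiology
RoxygenNote: 7.3.3
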