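Package: shapeqtl
Title: Mapping Quantitative Trait Loci for Morphological Shape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interval mapping of quantitative trait loci (QTLs) that control
    morphological shape in a backcross. Binary shape silhouettes are jointly
    aligned by steepest-descent minimisation of a pairwise image-difference
    energy, embedded as signed distance functions whose lexicographically
    stacked values form a high-dimensional phenotype matrix, and analysed
    with a two-component multivariate-normal mixture model fitted by EM.
    Mixture weights are the conditional QTL-genotype probabilities given
    flanking markers under the Haldane map function; significance of the
    likelihood-ratio profile is calibrated by permutation. A full synthetic
    simulator generates parametric leaf silhouettes and backcross
    populations so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
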