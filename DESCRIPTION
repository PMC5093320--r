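Package: mtalign
Title: Microtubule Self-Organization in Shaped Cells: Simulation and
    Image-Based Alignment Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how epithelial cell shape organizes the
    sub-apical microtubule (MT) cytoskeleton.  Provides an event-driven
    continuous-time Markov chain simulator of MT dynamic instability in
    two-dimensional cells of prescribed eccentricity, with angle-dependent
    zipping/crossover/catastrophe rules for MT-MT and MT-boundary
    collisions; an automated image-analysis pipeline that quantifies MT
    alignment (MTSD) and deviation from the cell long axis (MTDEV) from
    fluorescence images and per-cell label masks using 5x5 Sobel gradient
    direction histograms fitted with an axial Von Mises distribution; and
    a synthetic-data generator producing filament images with known
    angular statistics so each component validates the other.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
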