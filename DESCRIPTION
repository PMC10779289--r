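Package: mitoscreen
Title: High-Content Quantification of Mitochondrial Superoxide from
    Multichannel Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open, tested pipeline for quantifying mitochondrial
    superoxide, a mitochondrial membrane-potential proxy, and
    mitochondrial area per cell from three-channel fluorescence images of
    96-well plates. Nuclei are segmented from the nuclear-dye channel,
    a cell region is grown around each nucleus, and a per-cell
    mitochondrial mask is derived from the mitochondrial-dye channel;
    the superoxide-reporter channel is background-corrected (rolling
    paraboloid "sliding parabola" filter, or empty-well subtraction) and
    summed strictly within the mitochondrial mask. Well- and
    condition-level normalizations (percent of control, plate-reader RFU
    per microgram protein, relative viability), two-group tests with
    confidence intervals, one-way ANOVA with Dunnett's comparisons,
    Pearson chi-squared for cohort tables, and four-parameter logistic
    dose-response fits with IC50 standard errors are provided, together
    with a synthetic plate generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    mvtnorm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
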