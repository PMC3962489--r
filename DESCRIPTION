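Package: polyseg
Title: Chromosome Pairing Models and Marker Segregation Analysis for
    Synthetic Allotetraploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring chromosome-pairing behaviour in newly
    formed allotetraploids from single-locus marker segregation data.
    Implements the five classical tetraploid pairing models (gametic
    ratios, progeny genotype frequencies, expected apparent
    heterozygosity), detection-power and goodness-of-fit statistics for
    marker panels (exact binomial confidence intervals, Williams-corrected
    G-tests, heterogeneity G-tests), direct estimation of the preferential
    pairing factor from backcross marker data under bivalent or
    quadrivalent double-reduction assumptions, a tetraploid meiosis and
    phenotype simulator for power and recovery studies, and variance-based
    quantitative-genetic analyses (variance-homogeneity tests, coefficient
    of variation intervals, broad-sense heritability, nested variance
    components).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    lme4,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
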