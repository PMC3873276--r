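Package: shootDDI
Title: Molecular Phenotyping of Shoot Maturation in Sympodial Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying developmental maturation of plant shoot
    tissues from bulk RNA-seq counts and for dissecting single-gene dosage
    effects on flowering. Implements a Digital Differentiation Index (DDI)
    workflow that calibrates stage-peaked marker genes from a staged meristem
    atlas and scores the maturation state of unknown samples; a
    negative-binomial differential-expression stack (trimmed mean of M-values
    normalization, conditional-likelihood dispersion estimation, exact tests);
    a 12-category gene-action classifier for heterozygote versus parental
    genotype trios (additive, dominant, recessive, overdominant,
    underdominant); nonparametric statistics for shoot-architecture traits;
    and a synthetic-data generator with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
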