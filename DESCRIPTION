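Package: introgsel
Title: Genome-Wide Strength and Density of Selection Against Archaic Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the genome-wide average strength (s) and exonic density (mu)
    of purifying selection against introgressed archaic alleles, together with the
    effective initial admixture proportion (p0), from per-SNP introgressed-allele
    frequencies, an exon annotation and a genetic map. Implements the closed-form
    expected frequency of a neutral introgressed allele under linked purifying
    selection (autosomal and X-chromosomal transmission), nearest-selected-exon
    mixture predictions, grid-search inference by residual sum of squares with an
    analytic profile over p0, blockwise bootstrap confidence intervals, forward
    Wright-Fisher simulations of deleterious-allele accumulation in a small donor
    population, and a synthetic-data generator emulating the required input files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
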