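Package: trioburden
Title: De Novo and Inherited Variant Burden Analysis in Trio Exome Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A "genetic autopsy" toolkit for trio (proband plus both parents)
    exome cohorts. Calls de novo mutations and transmitted parental-mosaic
    variants from trio genotypes with allele-balance and depth quality
    control; computes per-gene expected de novo mutation counts from a
    trinucleotide-context mutation-rate model; tests observed-versus-expected
    burden with one-sided exact Poisson tests and case/control carrier burden
    with two-sided Fisher exact tests (conditional-MLE odds ratios); tests
    overtransmission of deleterious heterozygous parental variants with exact
    binomial tests; and tests deleteriousness-stratified protein-interaction
    edge enrichment with resampling nulls. Includes a synthetic trio-cohort
    generator (toy coding genome, read-level allele-depth evidence, injected
    truth tables) so every stage is testable without access to protected
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
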