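Package: sexbiome
Title: Sex-Biased Screening of Amplicon Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing male and female host-associated microbiomes
    from 16S amplicon sequence variant (ASV) count tables: sample exclusion
    and rarefaction to a fixed depth, alpha diversity (Shannon) with
    Wilcoxon/FDR testing, beta diversity (Bray-Curtis, weighted UniFrac),
    PCoA ordination and PERMANOVA, and a male-enrichment index
    i = (M - F)/M with a pseudocount floor and a cross-species consistency
    screen for ASVs recurrently enriched in males.  Includes a
    Dirichlet-multinomial generator of sex-stratified multi-species count
    tables with known spike-ins and a recovery harness quantifying the
    screen's sensitivity and null behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
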