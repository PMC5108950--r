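Package: panmix
Title: Population Genetic Diversity, Demography and Differentiation for
    Sequence and SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marine population genetics from mitochondrial
    sequence alignments and reduced-representation SNP genotype matrices.
    Implements haplotype collapsing, diversity indices and rarefaction,
    minimum spanning haplotype networks, Tajima's D and Fu's Fs neutrality
    tests with coalescent-simulation p-values, mismatch-distribution
    analysis under the sudden demographic expansion model with
    parametric-bootstrap goodness-of-fit tests, pairwise Phi-ST from
    AMOVA with permutation tests and Benjamini-Hochberg correction,
    RADseq-style read and locus filters (chimera motifs, first SNP per
    locus, missingness, minor allele frequency), Hardy-Weinberg exact
    screening, Weir-Cockerham FST, Hedrick G'ST and Jost's D with
    across-locus bootstrap confidence intervals, and a coalescent /
    Balding-Nichols simulation engine supplying null distributions and
    synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
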