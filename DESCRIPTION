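Package: asmqc
Title: Assembly Completeness, Comparison and Substitution-Rate Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control and comparative analysis of chromosome-level
    genome assemblies, built around the analyses used to characterise the
    Saanen_v1 goat assembly against the ARS1 reference. Provides
    per-chromosome accounting of gaps, ungapped length, N50 and phred-scaled
    consensus quality (QV); detection of telomeric (TTAGGG)n tracts by exact
    hexamer seeding combined with DUST low-complexity masking, and of
    centromeric satellite arrays from repeat annotations; k-mer spectrum
    construction and genome-size estimation; detection of large (>1 Mb)
    inversions and misplacements plus size-filtered structural variants from
    whole-genome alignments; classification of SNP-chip probe positional
    discrepancies between assemblies via a longest-increasing-subsequence
    rank test; and maximum-likelihood GTR+Gamma substitution-rate estimation
    on a fixed four-taxon topology with Y-versus-autosome rate comparison
    and male mutation bias. Seeded simulators generate every input format so
    the whole pipeline is testable on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
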