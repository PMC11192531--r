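Package: pansat
Title: Pan-Repertoire Saturation Analysis for Large Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the size and structure of pan-gene-family
    repertoires ("pan-genomes" of a single gene family) from gene
    presence/absence data across individuals. Implements exact average
    gene-accumulation (rarefaction) curves over all sub-sample choices via a
    hypergeometric closed form, least-squares fitting of the generalized
    harmonic saturation model y = alpha * H(x, beta), open/closed repertoire
    classification, extrapolation of total repertoire size through the
    Riemann zeta function, and the minimal sample size required to capture a
    given fraction of the repertoire. Also provides core/shell/cloud
    occupancy partitioning, cross-population sharing tallies, per-exon
    nucleotide diversity statistics (pairwise theta-pi and Watterson's
    theta-w) from VCF genotypes, and a synthetic-data generator producing
    presence/absence matrices, overdispersed read counts and neutral-model
    SNP genotypes for testing every stage without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
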