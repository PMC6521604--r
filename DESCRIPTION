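Package: polymiR
Title: Genotype-Aware Alignment and Quantification of miRNA Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-RNA-seq workflow that integrates per-sample genotype data
    into miRNA read alignment. The mature miRNA reference library is augmented
    with the alternative haplotypes of polymorphic miRNAs (polymiRs) taken from
    a VCF, reads are aligned with a constrained exact-core local aligner that
    tolerates trimmed and tailed extremities, cross-mapping reads are
    disambiguated by scoring 5'/3' editing events, isomiRs are annotated with
    the standard trimming/tailing label taxonomy, and polymiR alignments that
    contradict the sample's genotype are filtered out and reported. Results are
    exported as abundance tables and mirGFF3. A seeded synthetic-fixture
    generator produces toy reference bundles and reads with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
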