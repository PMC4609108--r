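Package: exonLDM
Title: Isoform and Gene Expression from Exon-Level RNA-Seq Counts via a
    Latent Dirichlet-Multinomial Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates gene- and isoform-level RNA-Seq expression from
    exon-level fragment counts with a latent Dirichlet-Multinomial model
    fitted by variational EM. Gene annotations are expanded into disjoint
    exon units, junction exons and an appended noise isoform; per-lane
    transcriptome alignments are converted into length-normalized exon
    count matrices; isoform fractions and isoform- and exon-specific read
    sequencing rates are estimated per gene using the technical-replicate
    information of multiple lanes of a single library; expression is
    reported as FPKM with Monte-Carlo measurement uncertainty. A seeded
    generative simulator produces count-level and read-level (FASTQ/SAM)
    data with ground truth for testing and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
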