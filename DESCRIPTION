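Package: stephseq
Title: Multiplex Amplicon Sequencing Surveillance of Insecticide
    Resistance in Anopheles stephensi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for targeted amplicon sequencing (Amp-seq) surveillance
    of insecticide resistance and genetic diversity in Anopheles stephensi.
    Implements the full desk-side pipeline for pooled, inline dual-barcoded
    paired-end reads: panel definition and read simulation, barcode/primer
    demultiplexing with per-amplicon coverage accounting, amplicon-targeted
    alignment and pileup construction, dual-caller SNP/indel calling with
    depth, allele-depth and cross-pool replication filters, alternate-allele
    fraction genotype classification, codon-level effect annotation with
    cross-species resistance-marker numbering (kdr/vgsc, rdl, ace1, GSTe2),
    and population genetics on consensus haplotypes (nucleotide diversity,
    haplotype diversity, Tajima's D, minimum-spanning haplotype networks,
    neighbour-joining trees).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
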