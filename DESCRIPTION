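Package: chiptargets
Title: Consensus Peaks, Target Annotation, Pol II Occupancy and qPCR Fold
    Changes for Transcription-Factor ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrative downstream analysis of transcription-factor ChIP-seq
    peak calls: derivation of consensus binding sites shared between two
    replicate peak sets under a base-pair proximity rule, annotation of peaks
    to their nearest RefSeq-style gene with promoter/exon/intron/downstream/
    intergenic location categories, quantification of RNA polymerase II
    occupancy over gene regions in RPKM with peak-extension handling,
    classification of target genes into transcriptional-status tiers relative
    to a housekeeping reference gene, capped IUPAC consensus-motif counting in
    peak sequences, and RT-qPCR/ChIP-qPCR delta-Ct fold-change statistics.
    Includes a deterministic synthetic-data generator that plants known
    location categories, occupancy tiers, motifs and expression fold changes
    so every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
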