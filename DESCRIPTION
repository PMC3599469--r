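Package: favr
Title: Filtering and Annotation of Rare Variants Using Comparator Alignment Evidence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shortlists rare germline single-nucleotide variants from massively
    parallel sequencing data by inspecting read-level signatures in alignment
    files. The Rare and True Filter discards candidate variants whose
    alternate-allele signature recurs across a panel of unrelated comparator
    BAM files (recurrent signals are either common variants or systematic
    mapping artefacts, neither of interest under a rare-variant disease
    model). The PE Bias Detector removes calls supported only by the short
    mate of imbalanced paired-end chemistries (for example 50/35-base SOLiD
    pairs), and the Family Annotate Tool adds read-level evidence from
    relatives' alignments without removing any call. The package also
    implements two assessment procedures (observed/expected shared variants
    between first cousins, and a known-variant sensitivity projection) and a
    seeded synthetic cohort generator producing reference FASTA, per-sample
    BAM and candidate VCF files with ground truth, so the whole pipeline can
    be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
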