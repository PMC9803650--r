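Package: diagindel
Title: Diagnostic InDel Marker Discovery and In-Silico Validation for Hybrid Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts group-diagnostic insertion/deletion (InDel) polymorphisms
    from a multi-sample VCF of two population groups, annotates them by genomic
    context (intron, exon, UTR, splice sites, ...), designs agarose-resolvable
    PCR marker candidates under amplicon-size, melting-temperature and GC
    constraints, and classifies parental versus F1-hybrid individuals from
    codominant band patterns, including an allelic-dropout model. A synthetic
    data generator produces toy reference genomes, two-group diploid genotype
    sets with planted diagnostic InDels, and simulated F1 crosses, so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
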