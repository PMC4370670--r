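Package: apafeedback
Title: Alternative Polyadenylation Gating of Intronic miRNA Host-Gene Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how alternative polyadenylation (APA) modulates
    negative feedback of intronic microRNAs on their host genes. Classifies
    miRNAs by genomic context and host-targeting status via 7mer-m8/7mer-A1
    seed-match scanning of host 3'UTRs, builds a poly(A)-site catalog from
    EST-style and RNA-Seq untemplated-tail evidence with an internal-priming
    filter and 40-nt clustering, scans canonical poly(A) signals and their
    positional distributions, calls differential 3'UTR shortening or
    lengthening between two RNA-Seq conditions with per-region binomial tests
    and a median-index rule, and tests enrichment of APA-machinery genes among
    host-targeting miRNA targets. Includes a ground-truthed synthetic-data
    generator exercising every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
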