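Package: primatx
Title: Bacterial Primary Transcriptome Analysis from Differential RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial primary transcriptomes from
    differential RNA-seq (dRNA-seq). Calls transcription start sites (TSS)
    from strand-specific read 5'-end count tracks by contrasting TEX-treated
    libraries against processed-end background with replicate-assisted
    background subtraction; classifies TSSs into gene-leading, internal,
    antisense and non-coding categories and summarises 5'-UTR architecture;
    tests TSS-level differential promoter activity between conditions with
    trimmed-mean-of-M-values normalisation and a negative-binomial exact
    test; scans 5'-UTRs for CsrA/Rsm binding sites and promoters for IUPAC
    motifs; calls flexible genomic islands from pairwise synteny breaks; and
    generates fully synthetic genomes, planted TSS truth sets and count
    tracks so the whole pipeline is testable without external data.
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
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
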