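Package: bivalentia
Title: Bivalent Promoter Classification, Chromatin Occupancy
    Redistribution, and FACS-Sort CRISPR Screen Analysis
Version: 0.1.0
Authors@R:
    person("Bivalentia", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for peak-level epigenomic analysis of
    bivalent chromatin. Classifies gene promoters into bivalent, H3K4me3-only,
    H3K27me3-only and unmarked states from paired peak sets; tabulates reads
    in peaks, normalizes to reads per million (RPM), and computes per-gene
    knockout-versus-control log2 fold changes of chromatin marks; performs
    the occupancy-redistribution analysis (RPM coverage filter, per-peak
    change calls, gene-level rollup and group-composition statistics);
    analyses FACS-sorted pooled CRISPR knockout screens by exact-match sgRNA
    counting, enrichment scoring, RSA hypergeometric gene ranking and
    confidence tiering; and provides set-level integration utilities
    (Benjamini-Hochberg adjustment, differential-expression thresholding,
    overlap summaries, gene-effect co-dependency). A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
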