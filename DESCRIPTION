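Package: riboqc
Title: Quality Control and Anomaly Detection for Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable quality-control toolkit for ribosome profiling
    (Ribo-seq) and matched RNA-seq experiments. Ingests aligned reads (BAM),
    a genome annotation (GFF3 or GTF) and a genome sequence (FASTA), attaches
    a rich per-alignment attribute model (P-site position, gene, feature,
    reading frame, distances to translation start and stop, GC content,
    mapping uniqueness), infers P-site offsets per read length from metagene
    density around translation start sites, computes standard QC surfaces
    (read-length and GC distributions, feature percentages, triplet
    periodicity, metagene profiles, library complexity, RPKM and
    translational efficiency), flags anomalous samples with four independent
    strategies (expert thresholds, Tukey's fence across user samples,
    percent error against designated controls, Tukey's fence against a
    reference metric table), and emits reproducible TSV/PNG/HTML reports.
    A built-in simulator generates miniature genomes, annotations and
    aligned reads with controlled periodicity so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
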