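# Fixtures are generated in code; heavier ones are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

toy_gff3_lines <- function() {
  c("##gff-version 3",
    "chrT\ttest\tgene\t101\t300\t.\t+\t.\tID=gA",
    "chrT\ttest\tmRNA\t101\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chrT\ttest\texon\t101\t180\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "chrT\ttest\texon\t221\t300\t.\t+\t.\tID=gA.t1.e2;Parent=gA.t1",
    "chrT\ttest\tfive_prime_UTR\t101\t130\t.\t+\t.\tID=gA.t1.u5;Parent=gA.t1",
    "chrT\ttest\tCDS\t131\t180\t.\t+\t0\tID=gA.t1.cds;Parent=gA.t1",
    "chrT\ttest\tCDS\t221\t251\t.\t+\t1\tID=gA.t1.cds;Parent=gA.t1",
    "chrT\ttest\tthree_prime_UTR\t252\t300\t.\t+\t.\tID=gA.t1.u3;Parent=gA.t1",
    "chrT\ttest\tmRNA\t101\t300\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chrT\ttest\texon\t101\t300\t.\t+\t.\tID=gA.t2.e1;Parent=gA.t2",
    "chrT\ttest\tCDS\t131\t160\t.\t+\t0\tID=gA.t2.cds;Parent=gA.t2",
    "chrT\ttest\tgene\t401\t560\t.\t-\t.\tID=gB",
    "chrT\ttest\tmRNA\t401\t560\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chrT\ttest\texon\t401\t460\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1",
    "chrT\ttest\texon\t501\t560\t.\t-\t.\tID=gB.t1.e2;Parent=gB.t1",
    "chrT\ttest\tCDS\t449\t460\t.\t-\t0\tID=gB.t1.cds;Parent=gB.t1",
    "chrT\ttest\tCDS\t501\t548\t.\t-\t0\tID=gB.t1.cds;Parent=gB.t1",
    "chrT\ttest\tgene\t570\t590\t.\t+\t.\tID=rC",
    "chrT\ttest\trRNA\t570\t590\t.\t+\t.\tID=rC.t1;Parent=rC",
    "chrT\ttest\texon\t570\t590\t.\t+\t.\tID=rC.t1.e1;Parent=rC.t1")
}

toy_fasta_path <- function() {
  p <- file.path(tempdir(), "riboqc_toy.fa")
  if (!file.exists(p)) {
    writeLines(c(">chrT", strrep("ACGTTGCA", 75)), p)
  }
  p
}

toy_gff3_path <- function() {
  p <- file.path(tempdir(), "riboqc_toy.gff3")
  if (!file.exists(p)) writeLines(toy_gff3_lines(), p)
  p
}

toy_annotation <- function() {
  if (is.null(.fixture_cache$toy_ann)) {
    .fixture_cache$toy_ann <- parse_annotation(toy_gff3_path(), toy_fasta_path())
  }
  .fixture_cache$toy_ann
}

# GFF3 records as a plain data frame for the brute-force feature oracle.
toy_gff3_records <- function() {
  lines <- toy_gff3_lines()[-1]
  f <- strsplit(lines, "\t")
  gene_of <- c(gA = "gA", gA.t1 = "gA", gA.t2 = "gA", gB = "gB", gB.t1 = "gB",
               rC = "rC", rC.t1 = "rC")
  id <- sub(".*ID=([^;]+).*", "\\1", lines)
  parent <- ifelse(grepl("Parent=", lines), sub(".*Parent=([^;]+).*", "\\1", lines), NA)
  gid <- ifelse(is.na(parent), id, unname(gene_of[parent]))
  data.frame(seqid = vapply(f, `[[`, "", 1),
             type = vapply(f, `[[`, "", 3),
             start = as.integer(vapply(f, `[[`, "", 4)),
             end = as.integer(vapply(f, `[[`, "", 5)),
             strand = vapply(f, `[[`, "", 7),
             gene_id = gid, stringsAsFactors = FALSE)
}

# One moderately sized simulated study shared across test files.
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    spec <- sim_spec(seed = 101, n_reads = 6000)
    gsim <- simulate_genome(spec, file.path(tempdir(), "riboqc_shared_sim"))
    ann <- parse_annotation(gsim$gff3, gsim$fasta)
    bam <- simulate_reads(gsim, "s1", "Ribo", seed = 102)
    tab <- load_alignments(bam, "s1", "Ribo")
    offs <- build_offset_table(tab, ann)
    atab <- annotate_alignments(tab, ann, offs)
    .fixture_cache$sim <- list(spec = spec, gsim = gsim, ann = ann, bam = bam,
                               tab = tab, offs = offs, atab = atab)
  }
  .fixture_cache$sim
}

# Minimal in-memory alignment table builder for unit tests.
mk_alignments <- function(range_start, length, strand = "+", chrom = "chrT",
                          sample = "s", exp = "Ribo", mapq = 50L, gc = 0.5) {
  n <- base::length(range_start)
  as_alignment_table(tibble::tibble(
    seqnames = rep_len(chrom, n), range_start = as.integer(range_start),
    range_end = as.integer(range_start + length), strand = rep_len(strand, n),
    sample = rep_len(sample, n), exp = rep_len(exp, n),
    length = as.integer(rep_len(length, n)), gc = rep_len(gc, n),
    mapq = as.integer(rep_len(mapq, n))))
}
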