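test_that("toy GFF3 parses to the expected gene/transcript/CDS structure", {
  ann <- toy_annotation()
  expect_s3_class(ann, "GenomeAnnotation")
  expect_equal(ann$source_dialect, "GFF3")
  expect_setequal(names(ann$genes), c("gA", "gB", "rC"))
  expect_length(ann$genes$gA$transcripts, 2L)

  t1 <- ann$genes$gA$transcripts[[1]]
  expect_equal(t1$transcript_id, "gA.t1")
  expect_equal(t1$exon_start, c(100L, 220L))
  expect_equal(t1$exon_end, c(180L, 300L))
  expect_equal(t1$length_t, 160L)
  expect_equal(t1$cds_start_t, 30L)
  expect_equal(t1$cds_stop_t, 108L)  # first nt of the stop codon

  tb <- ann$genes$gB$transcripts[[1]]
  expect_equal(tb$strand, "-")
  expect_equal(tb$exon_start, c(500L, 400L))  # 5'-most exon first
  expect_equal(tb$cds_start_t, 12L)
  expect_equal(tb$cds_stop_t, 69L)

  # non-coding transcript carried without CDS coordinates
  rc <- ann$genes$rC$transcripts[[1]]
  expect_true(is.na(rc$cds_start_t) && is.na(rc$cds_stop_t))
})

test_that("GTF and GFF3 renderings of one locus set parse identically", {
  gsim <- simulate_genome(sim_spec(n_genes = 5, seed = 11),
                          formats = c("gff3", "gtf"))
  a1 <- parse_annotation(gsim$gff3, gsim$fasta)
  a2 <- parse_annotation(gsim$gtf, gsim$fasta)
  expect_equal(a2$source_dialect, "GTF")
  expect_setequal(names(a1$genes), names(a2$genes))
  for (g in names(a1$genes)) {
    t1 <- a1$genes[[g]]$transcripts[[a1$genes[[g]]$major]]
    t2 <- a2$genes[[g]]$transcripts[[a2$genes[[g]]$major]]
    expect_equal(unclass(t1), unclass(t2), info = g)
  }
})

test_that("degenerate annotation inputs raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_error(parse_annotation(empty, toy_fasta_path()), "no records")

  mismatched <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gsub("chrT", "chrZ", toy_gff3_lines()), mismatched)
  expect_error(parse_annotation(mismatched, toy_fasta_path()), "chrZ")

  expect_error(parse_annotation("nope.gff3", toy_fasta_path()), "not found")
})

test_that("major isoform: longest CDS, then spliced length, then id", {
  ann <- toy_annotation()
  # gA.t1 CDS 81 nt beats gA.t2 CDS 30 nt
  expect_equal(ann$genes$gA$major, 1L)
  expect_equal(ann$genes$gB$major, 1L)  # only transcript

  mk <- function(id, len, cds) {
    t <- riboqc:::new_transcript_model(id, "chrT", "+", 0L, len)
    if (!is.na(cds)) {
      t$cds_start_t <- 0L
      t$cds_stop_t <- as.integer(cds - 3L)
    }
    t
  }
  gene <- structure(list(gene_id = "g", chromosome = "chrT", strand = "+",
                         transcripts = list(mk("tx_b", 900L, 300L),
                                            mk("tx_a", 700L, 450L))),
                    class = "GeneModel")
  expect_equal(select_major_isoform(gene), 2L)  # 450 > 300 nt CDS
  gene$transcripts <- list(mk("tx_b", 900L, 300L), mk("tx_a", 700L, 300L))
  expect_equal(select_major_isoform(gene), 1L)  # CDS tie -> longer transcript
  gene$transcripts <- list(mk("tx_b", 900L, 300L), mk("tx_a", 900L, 300L))
  expect_equal(select_major_isoform(gene), 2L)  # full tie -> smaller id
  # coding beats non-coding regardless of length
  gene$transcripts <- list(mk("tx_nc", 2000L, NA), mk("tx_c", 300L, 150L))
  expect_equal(select_major_isoform(gene), 2L)
})

test_that("coordinate maps invert on exonic positions and reject introns", {
  ann <- toy_annotation()
  t1 <- ann$genes$gA$transcripts[[1]]
  expect_equal(genomic_to_transcript(t1, 100L), 0L)
  expect_true(is.na(genomic_to_transcript(t1, 200L)))  # intron
  expect_true(is.na(genomic_to_transcript(t1, 50L)))   # intergenic

  tb <- ann$genes$gB$transcripts[[1]]
  # last genomic base of the 5'-most exon block, minus strand
  expect_equal(genomic_to_transcript(tb, 559L),
               bf_genomic_to_transcript(tb, 559L))
  expect_equal(genomic_to_transcript(tb, 500L), 59L)

  withr::with_seed(77, {
    for (i in 1:40) {
      t <- random_transcript(strand = sample(c("+", "-"), 1),
                             n_exons = sample(1:4, 1))
      walk <- enumerate_tx_positions(t)
      tp <- genomic_to_transcript(t, walk)
      expect_equal(tp, seq_along(walk) - 1L)
      expect_equal(transcript_to_genomic(t, tp), walk)
      if (length(t$exon_start) > 1) {
        intron <- t$exon_end[order(t$exon_start)][1]  # just past an exon
        expect_true(is.na(genomic_to_transcript(t, intron)))
      }
    }
  })
})

test_that("feature assignment matches a brute-force record scan", {
  ann <- toy_annotation()
  recs <- toy_gff3_records()
  grid <- expand.grid(pos = seq(90L, 600L, by = 7L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  got <- assign_features(ann, rep("chrT", nrow(grid)), grid$strand, grid$pos)
  for (i in seq_len(nrow(grid))) {
    want <- bf_assign_feature(recs, default_feature_priority(),
                              "chrT", grid$strand[i], grid$pos[i])
    expect_equal(c(feature = got$feature[i], gene_id = got$gene_id[i]), want,
                 info = sprintf("pos=%d strand=%s", grid$pos[i], grid$strand[i]))
  }
  # specificity and strandness anchors
  expect_equal(assign_feature(ann, "chrT", "+", 140L),
               c(feature = "CDS", gene_id = "gA"))
  expect_equal(assign_feature(ann, "chrT", "+", 110L),
               c(feature = "five_prime_UTR", gene_id = "gA"))
  expect_equal(assign_feature(ann, "chrT", "+", 10L),
               c(feature = "Other", gene_id = "Other"))
  expect_equal(assign_feature(ann, "chrT", "-", 140L),
               c(feature = "Other", gene_id = "Other"))
  expect_equal(assign_feature(ann, "chrT", "+", 575L),
               c(feature = "rRNA", gene_id = "rC"))
})

test_that("parsing is invariant to record order in the file", {
  ref <- toy_annotation()
  withr::with_seed(5, {
    for (i in 1:3) {
      shuf <- withr::local_tempfile(fileext = ".gff3")
      body <- toy_gff3_lines()[-1]
      writeLines(c("##gff-version 3", sample(body)), shuf)
      ann <- parse_annotation(shuf, toy_fasta_path())
      for (g in names(ref$genes)) {
        expect_equal(ann$genes[[g]]$major, ref$genes[[g]]$major)
        expect_equal(
          unclass(ann$genes[[g]]$transcripts[[ann$genes[[g]]$major]]),
          unclass(ref$genes[[g]]$transcripts[[ref$genes[[g]]$major]]))
      }
    }
  })
})
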