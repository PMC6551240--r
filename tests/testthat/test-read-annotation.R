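write_toy_bam <- function(lines, stem = tempfile("toy_")) {
  sam <- paste0(stem, ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:600", lines), sam)
  Rsamtools::asBam(sam, stem, overwrite = TRUE, indexDestination = TRUE)
}

sam_line <- function(qname, flag, pos1, len = 28L, mapq = 50L,
                     cigar = paste0(len, "M"), rname = "chrT") {
  paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0,
        strrep("ACGT", ceiling(len / 4)) |> substr(1, len), "*", sep = "\t")
}

test_that("BAM loading keeps primary mapped alignments only", {
  bam <- write_toy_bam(c(
    sam_line("r1", 0, 110), sam_line("r2", 0, 120), sam_line("r3", 16, 130),
    sam_line("r4", 0, 140), sam_line("r5", 0, 150),
    sam_line("s1", 256, 110), sam_line("s2", 272, 120),   # secondary
    sam_line("u1", 4, 0, rname = "*", mapq = 0, cigar = "*")))
  tab <- suppressMessages(load_alignments(bam, "toy", "Ribo"))
  expect_s3_class(tab, "alignment_table")
  expect_equal(nrow(tab), 5L)
  expect_equal(unique(tab$length), 28L)  # 28 matched bases -> length 28
  expect_equal(tab$range_start[tab$strand == "+"][1], 109L)  # 0-based
  expect_equal(tab$range_end[1] - tab$range_start[1], 28L)

  empty <- write_toy_bam(character(0))
  expect_warning(etab <- load_alignments(empty, "e", "Ribo"), "no usable")
  expect_equal(nrow(etab), 0L)
})

test_that("GC content and MAPQ uniqueness follow their definitions", {
  expect_equal(compute_gc(c("ATGC", "GGGG", "ATNN")), c(0.5, 1.0, 0.0))
  expect_equal(compute_gc(Biostrings::DNAStringSet(c("ATGC", "GGGG"))),
               c(0.5, 1.0))
  expect_error(compute_gc(""), "empty")

  expect_true(classify_unique(50L))
  expect_false(classify_unique(1L))
  expect_false(classify_unique(49L))
  expect_true(classify_unique(255L, unique_mapq = 255L))
  expect_equal(classify_unique(c(50L, 0L, 50L)), c(TRUE, FALSE, TRUE))
})

test_that("P-site annotation anchors frame and distances at the start codon", {
  ann <- toy_annotation()
  offs <- offset_table(28L, 12L)
  # gA.t1 (+): cds_start_t = 30, cds_stop_t = 108, exon1 covers tpos 0..79
  reads <- mk_alignments(c(118L, 122L, 10L), 28L)
  out <- annotate_alignments(reads, ann, offs)
  # P-site exactly at the start codon's first nt
  expect_equal(out$pos[1], 130L)
  expect_equal(out$frame[1], 0L)
  expect_equal(out$start_dist[1], 30L)
  expect_equal(out$end_dist[1], 108L - 30L)
  expect_equal(out$gene[1], "gA")
  expect_equal(out$feature[1], "CDS")
  # P-site 4 nt downstream of the start codon
  expect_equal(out$frame[2], 1L)
  # intergenic P-site
  expect_equal(out$gene[3], "Other")
  expect_equal(out$feature[3], "Other")
  expect_true(is.na(out$frame[3]))
  expect_true(is.na(out$start_dist[3]) && is.na(out$end_dist[3]))

  # minus strand: 5' end is range_end - 1
  minus <- mk_alignments(532L, 28L, strand = "-")
  mout <- annotate_alignments(minus, ann, offs)
  expect_equal(mout$pos[1], 547L)  # tpos 0 + offset 12 -> genomic 559 - 12
  expect_equal(mout$frame[1], 0L)
  expect_equal(mout$start_dist[1], 12L)

  # offset walks across the exon junction in spliced space
  junction <- mk_alignments(175L, 28L)
  jout <- annotate_alignments(junction, ann, offs)
  expect_equal(jout$pos[1], 227L)  # tpos 75 + 12 = 87 -> exon2, not 175 + 12

  # tss anchor shifts the frame register by cds_start_t mod 3
  tss <- annotate_alignments(reads, ann, offs, frame_anchor = "tss")
  expect_equal(tss$frame[1], 30L %% 3L)
})

test_that("annotation is idempotent and frame matches brute-force walking", {
  fx <- shared_sim()
  again <- annotate_alignments(fx$atab, fx$ann, fx$offs)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(fx$atab))

  idx <- withr::with_seed(3, sample(nrow(fx$atab), 300))
  sub <- fx$atab[idx, ]
  for (i in seq_len(nrow(sub))) {
    if (sub$gene[i] == "Other") next
    t <- fx$ann$genes[[sub$gene[i]]]$transcripts[[
      fx$ann$genes[[sub$gene[i]]]$major]]
    expect_identical(sub$frame[i], bf_frame(t, sub$pos[i]),
                     info = paste("row", i))
  }
})

test_that("filter_and_group partitions records and validates attributes", {
  fx <- shared_sim()
  tab <- fx$atab

  cds <- filter_and_group(tab, filters = list(feature = "CDS"))
  expect_true(all(cds$all$feature == "CDS"))

  by_len <- filter_and_group(tab, filters = list(length = 27:29,
                                                 exp = "Ribo"),
                             group_by = "length")
  expect_lte(length(by_len), 3L)
  expect_equal(sum(vapply(by_len, nrow, integer(1))),
               sum(tab$length %in% 27:29 & tab$exp == "Ribo"))

  # partition property over an arbitrary grouping
  grp <- filter_and_group(tab, group_by = c("feature", "frame"))
  expect_equal(sum(vapply(grp, nrow, integer(1))), nrow(tab))
  expect_equal(names(grp), sort(names(grp)))

  expect_error(filter_and_group(tab, filters = list(bogus = 1)), "bogus")
  expect_error(filter_and_group(tab, group_by = "nope"), "nope")
})

test_that("alignment tables round-trip through TSV", {
  fx <- shared_sim()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_table(head(fx$atab, 50), p)
  back <- read_alignment_table(p)
  expect_true(isTRUE(attr(back, "annotated")))
  expect_equal(as.data.frame(back), as.data.frame(head(fx$atab, 50)),
               ignore_attr = TRUE)
})
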