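test_that("read length and GC distributions normalise per group", {
  tab <- mk_alignments(rep(100L, 10), 28L)
  one <- read_length_distribution(tab)
  expect_equal(one$fraction, 1)

  mixed <- dplyr::bind_rows(
    mk_alignments(rep(100L, 2), 27L),
    mk_alignments(rep(100L, 6), 28L),
    mk_alignments(rep(100L, 2), 29L))
  rld <- read_length_distribution(list(all = mixed))
  expect_equal(setNames(rld$fraction, rld$length),
               c(`27` = 0.2, `28` = 0.6, `29` = 0.2))

  # independent normalisation per group
  fx <- shared_sim()
  grp <- filter_and_group(fx$atab, group_by = "length")
  rld2 <- read_length_distribution(grp)
  sums <- tapply(rld2$fraction, rld2$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  gcd <- gc_distribution(tab)
  expect_equal(sum(gcd$count), 10L)
  expect_equal(gcd$count[gcd$bin_lo == 0.5], 10L)  # all reads at gc 0.5
  expect_warning(gc_distribution(list(empty = tab[0, ])), "empty")
})

test_that("feature percentages sum to 100 and follow the tally", {
  feats <- tibble::tibble(feature = c(rep("CDS", 80), rep("rRNA", 20)))
  tab <- mk_alignments(rep(100L, 100), 28L)
  tab$feature <- feats$feature
  fp <- feature_percentages(list(g = tab))
  expect_equal(setNames(fp$pct, fp$level), c(CDS = 80, rRNA = 20))

  single <- tab[tab$feature == "CDS", ]
  expect_equal(feature_percentages(list(g = single))$pct, 100)

  fx <- shared_sim()
  by_sample <- feature_percentages(filter_and_group(fx$atab,
                                                    group_by = "sample"))
  expect_true(all(abs(tapply(by_sample$pct, by_sample$group, sum) - 100) < 1e-9))

  # any attribute works as the tally key
  byframe <- feature_percentages(list(all = fx$atab), by = "frame")
  expect_lte(nrow(byframe), 4L)  # frames 0/1/2 (+ NA dropped)
})

test_that("frame periodicity recovers the generator's in-frame fraction", {
  tab <- mk_alignments(rep(100L, 10), 28L)
  tab$frame <- rep(0L, 10)
  expect_equal(unname(frame_periodicity(tab)), c(1, 0, 0),
               ignore_attr = TRUE)

  tab$frame <- c(rep(0L, 6), rep(1L, 2), rep(2L, 2))
  fr <- frame_periodicity(tab)
  expect_equal(unname(fr), c(0.6, 0.2, 0.2), ignore_attr = TRUE)
  expect_equal(sum(fr), 1)
  expect_equal(attr(fr, "n_reads"), 10L)

  fx <- shared_sim()
  f <- frame_periodicity(fx$atab)
  n <- attr(f, "n_reads")
  sigma <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(f[["f0"]] - fx$spec$in_frame), 3 * sigma + 1e-12)
  expect_equal(sum(f), 1)
})

test_that("metagene profiles spike at their anchors and subsample reproducibly", {
  ann <- toy_annotation()
  offs <- offset_table(28L, 12L)
  # P-sites all at the start codon
  at_start <- annotate_alignments(mk_alignments(rep(118L, 25), 28L), ann, offs)
  mg <- metagene_profile(at_start, ann, "start", c(-5L, 5L))
  expect_equal(mg$count[mg$position == 0], 25L)
  expect_equal(sum(mg$count), 25L)

  # P-sites 30 nt before the stop codon: tpos 78, 5' end tpos 66 -> gpos 166
  before_stop <- annotate_alignments(mk_alignments(rep(166L, 9), 28L), ann, offs)
  ms <- metagene_profile(before_stop, ann, "stop", c(-40L, 5L))
  expect_equal(ms$count[ms$position == -30], 9L)

  fx <- shared_sim()
  full <- metagene_profile(fx$atab, fx$ann, "start")
  same <- metagene_profile(fx$atab, fx$ann, "start", subsample = nrow(fx$atab))
  expect_equal(same, full)
  s1 <- metagene_profile(fx$atab, fx$ann, "start", subsample = 800, seed = 4)
  s2 <- metagene_profile(fx$atab, fx$ann, "start", subsample = 800, seed = 4)
  expect_identical(s1, s2)
  expect_equal(sum(s1$count <= full$count), nrow(full))  # subsample nested

  norm <- metagene_profile(fx$atab, fx$ann, "start", normalize = TRUE)
  expect_equal(sum(norm$fraction), 1)
})

test_that("complexity and duplication count distinct alignment tuples", {
  same <- mk_alignments(rep(100L, 8), 28L)
  expect_equal(complexity(same), 1 / 8)
  expect_equal(duplication(same), 1 - 1 / 8)

  distinct <- mk_alignments(seq(100L, 170L, by = 10L), 28L)
  expect_equal(complexity(distinct), 1)
  expect_equal(duplication(distinct), 0)

  known <- mk_alignments(rep(c(100L, 110L, 120L, 130L), times = c(3, 2, 1, 4)),
                         28L)
  expect_equal(complexity(known), 4 / 10)
  expect_warning(expect_true(is.na(complexity(same[0, ]))), "empty")
})

test_that("RPKM follows its formula and is scale-free in library size", {
  fx <- shared_sim()
  rp <- rpkm(fx$atab, fx$ann)
  # agreement with a direct per-gene computation
  g <- names(fx$ann$genes)[1]
  len <- fx$ann$genes[[g]]$transcripts[[fx$ann$genes[[g]]$major]]$length_t
  cnt <- sum(fx$atab$gene == g)
  expect_equal(rp$rpkm[rp$gene == g], cnt * 1e9 / (nrow(fx$atab) * len))
  expect_equal(rp$rpkm[rp$count == 0], rep(0, sum(rp$count == 0)))

  doubled <- bind_alignments(fx$atab, fx$atab)
  rp2 <- rpkm(doubled, fx$ann)
  expect_equal(rp2$rpkm, rp$rpkm)
})

test_that("translational efficiency is the RPKM ratio with guarded zeros", {
  te <- translational_efficiency(c(gA = 10, gB = 0, gC = 5),
                                 c(gA = 5, gB = 2, gC = 0))
  expect_equal(te$te[te$gene == "gA"], 2)
  expect_equal(te$te[te$gene == "gB"], 0)
  expect_true(is.na(te$te[te$gene == "gC"]))
  expect_true(te$undefined[te$gene == "gC"])

  pc <- translational_efficiency(c(g = 10), c(g = 0), pseudocount = 1)
  expect_equal(pc$te, 11)
  expect_false(pc$undefined)
})

test_that("summary table fields equal their direct computations", {
  fx <- shared_sim()
  st <- summary_table(fx$atab)
  expect_equal(nrow(st), 1L)
  expect_equal(st$total_alignments, nrow(fx$atab))
  expect_equal(st$pct_unique, 100 * mean(classify_unique(fx$atab$mapq)))
  expect_equal(st$complexity, complexity(fx$atab))
  expect_equal(st$duplication, duplication(fx$atab))
  fr <- frame_periodicity(fx$atab)
  expect_equal(st$periodicity, fr[["f0"]])
  expect_equal(st$f0 + st$f1 + st$f2, 1)
  fp <- feature_percentages(list(all = fx$atab))
  for (lv in fp$level) {
    expect_equal(st[[paste0("pct_", lv)]], fp$pct[fp$level == lv])
  }
  pct_cols <- grep("^pct_(?!unique)", colnames(st), perl = TRUE, value = TRUE)
  expect_equal(sum(unlist(st[1, pct_cols])), 100)

  # two identical samples give identical rows
  copy <- fx$atab
  copy$sample <- "s1_copy"
  both <- summary_table(bind_alignments(fx$atab, copy))
  expect_equal(unlist(both[1, -1][-1]), unlist(both[2, -1][-1]))

  # periodicity is computed for RNA too; exp column marks interpretability
  rna <- fx$atab
  rna$sample <- "rna"
  rna$exp <- "RNA"
  st2 <- summary_table(bind_alignments(fx$atab, rna))
  expect_equal(st2$exp, c("rna" = "RNA", "s1" = "Ribo")[st2$sample],
               ignore_attr = TRUE)
  expect_false(any(is.na(st2$periodicity)))
})

test_that("per-gene coverage export writes a valid bedGraph", {
  ann <- toy_annotation()
  offs <- offset_table(28L, 12L)
  atab <- annotate_alignments(mk_alignments(rep(118L, 3), 28L), ann, offs)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  cov <- gene_coverage(atab, ann, "gA", p)
  expect_equal(cov$count[cov$start == 130], 3L)
  lines <- readLines(p)
  expect_match(lines[1], "bedGraph")
  expect_equal(length(lines), nrow(cov) + 1L)
  expect_error(gene_coverage(atab, ann, "nope"), "unknown gene")
})
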