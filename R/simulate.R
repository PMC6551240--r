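#' Specification for a simulated Ribo-seq study
#'
#' Bundles every knob of the genome/read simulator: gene structure ranges,
#' contamination levels, per-length true P-site offsets, read-length mix,
#' in-frame fraction, start-codon pileup, library size, duplication rate and
#' mapping-uniqueness mix. Defaults describe a typical good-quality eukaryotic
#' footprinting library: 27-29 nt footprints with canonical ~12 nt 5'-to-P-site
#' offsets, 70% of P-sites in frame 0, mild rRNA/tRNA contamination.
#'
#' @param n_genes Number of protein-coding genes.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param n_reads Reads per simulated sample.
#' @param in_frame Probability that a footprint's P-site lands in frame 0;
#'   the remainder splits evenly over frames 1 and 2.
#' @param offsets Named integer vector, read length -> true P-site offset (nt).
#' @param length_probs Named numeric vector, read length -> sampling
#'   probability (must sum to 1 and share names with `offsets`).
#' @param utr5_range,utr3_range UTR length ranges (nt).
#' @param cds_codons Range of CDS length in codons (start and stop included).
#' @param intergenic_range Spacer length range between loci (nt).
#' @param multi_exon_frac Fraction of genes given more than one exon.
#' @param max_exons Maximum exons per gene.
#' @param intron_range Intron length range (nt).
#' @param rrna_fraction,trna_fraction Fraction of Ribo-seq reads drawn from
#'   rRNA / tRNA loci.
#' @param n_rrna,n_trna,rrna_length,trna_length Contaminant locus layout.
#' @param start_pileup Extra probability mass placed on the start codon,
#'   emulating initiation pileup.
#' @param duplication_rate Probability that a read is a duplicate copy of
#'   another read in the library.
#' @param unique_frac Fraction of alignments written with the
#'   uniquely-mapped MAPQ (50); the rest get MAPQ 1.
#' @param rna_length_range RNA-seq read length range (nt).
#' @param chrom_name Chromosome name of the simulated genome.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 20, seed = 1, n_reads = 3000, in_frame = 0.7,
                     offsets = c(`27` = 11L, `28` = 12L, `29` = 13L),
                     length_probs = c(`27` = 0.25, `28` = 0.5, `29` = 0.25),
                     utr5_range = c(60, 120), cds_codons = c(100, 200),
                     utr3_range = c(60, 120), intergenic_range = c(200, 400),
                     multi_exon_frac = 0.3, max_exons = 3,
                     intron_range = c(50, 150),
                     rrna_fraction = 0.05, trna_fraction = 0.02,
                     n_rrna = 2, n_trna = 2,
                     rrna_length = 600, trna_length = 80,
                     start_pileup = 0.1, duplication_rate = 0.1,
                     unique_frac = 0.85, rna_length_range = c(36, 50),
                     chrom_name = "chr1") {
  stopifnot(
    n_genes >= 1, in_frame >= 0, in_frame <= 1,
    rrna_fraction >= 0, trna_fraction >= 0,
    rrna_fraction + trna_fraction <= 1,
    duplication_rate >= 0, duplication_rate < 1,
    unique_frac >= 0, unique_frac <= 1,
    start_pileup >= 0, start_pileup <= 1,
    abs(sum(length_probs) - 1) < 1e-9,
    setequal(names(offsets), names(length_probs))
  )
  structure(list(
    n_genes = n_genes, seed = seed, n_reads = n_reads, in_frame = in_frame,
    offsets = offsets, length_probs = length_probs,
    utr5_range = utr5_range, cds_codons = cds_codons, utr3_range = utr3_range,
    intergenic_range = intergenic_range, multi_exon_frac = multi_exon_frac,
    max_exons = max_exons, intron_range = intron_range,
    rrna_fraction = rrna_fraction, trna_fraction = trna_fraction,
    n_rrna = n_rrna, n_trna = n_trna,
    rrna_length = rrna_length, trna_length = trna_length,
    start_pileup = start_pileup, duplication_rate = duplication_rate,
    unique_frac = unique_frac, rna_length_range = rna_length_range,
    chrom_name = chrom_name
  ), class = "sim_spec")
}

rint <- function(range) sample(range[1]:range[2], 1L)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Genomic blocks (0-based half-open, genomically ascending) covered by the
# transcript interval [a, b).
tx_blocks <- function(t, a, b) {
  res <- list()
  for (j in seq_along(t$exon_start)) {
    cb <- t$cumbefore[j]
    w <- t$exon_end[j] - t$exon_start[j]
    lo <- max(a, cb); hi <- min(b, cb + w)
    if (lo >= hi) next
    res[[length(res) + 1L]] <- if (t$strand == "+") {
      c(t$exon_start[j] + lo - cb, t$exon_start[j] + hi - cb)
    } else {
      c(t$exon_end[j] - (hi - cb), t$exon_end[j] - (lo - cb))
    }
  }
  m <- do.call(rbind, res)
  m[order(m[, 1]), , drop = FALSE]
}

non_stop_codons <- function() {
  codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                            c("A","C","G","T"), paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

simulate_one_gene <- function(spec, gene_id, g0) {
  u5 <- rint(spec$utr5_range)
  n_codons <- rint(spec$cds_codons)
  u3 <- rint(spec$utr3_range)
  cds_len <- 3L * n_codons
  cds_seq <- paste0("ATG",
                    paste(sample(non_stop_codons(), n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    "TAA")
  tx_seq <- paste0(random_dna(u5), cds_seq, random_dna(u3))
  tx_len <- u5 + cds_len + u3

  k <- if (stats::runif(1) < spec$multi_exon_frac && spec$max_exons > 1) {
    sample(2:spec$max_exons, 1L)
  } else 1L
  cuts <- if (k > 1L) sort(sample(seq(30L, tx_len - 30L), k - 1L)) else integer(0)
  exon_tx_start <- c(0L, cuts)
  exon_tx_end <- c(cuts, tx_len)
  exon_w <- exon_tx_end - exon_tx_start
  intron_w <- if (k > 1L) {
    vapply(seq_len(k - 1L), function(i) rint(spec$intron_range), integer(1))
  } else integer(0)

  strand <- sample(c("+", "-"), 1L)
  span <- sum(exon_w) + sum(intron_w)
  # gene sequence in transcript orientation, introns interleaved
  pieces <- character(0)
  for (j in seq_len(k)) {
    pieces <- c(pieces, substr(tx_seq, exon_tx_start[j] + 1L, exon_tx_end[j]))
    if (j < k) pieces <- c(pieces, random_dna(intron_w[j]))
  }
  gene_seq_tx <- paste(pieces, collapse = "")
  gene_seq <- if (strand == "+") gene_seq_tx else revcomp(gene_seq_tx)

  # exon offsets within the gene span, transcript orientation
  o <- cumsum(c(0L, head(exon_w + c(intron_w, 0L), -1L)))
  gstart0 <- if (strand == "+") g0 + o else g0 + span - o - exon_w
  gend0 <- gstart0 + exon_w
  tx <- new_transcript_model(paste0(gene_id, ".t1"), spec$chrom_name, strand,
                             gstart0, gend0,
                             cds_start_t = u5, cds_stop_t = u5 + cds_len - 3L)
  list(gene_id = gene_id, type = "mRNA", tx = tx, seq = gene_seq,
       span = span, u5 = u5, cds_len = cds_len, tx_len = tx_len)
}

gff3_attrs <- function(id = NULL, parent = NULL) {
  a <- c(if (!is.null(id)) paste0("ID=", id),
         if (!is.null(parent)) paste0("Parent=", parent))
  paste(a, collapse = ";")
}

gene_annotation_rows <- function(spec, g, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  t <- g$tx
  chrom <- spec$chrom_name
  gspan <- c(min(t$exon_start), max(t$exon_end))
  tx_type <- if (g$type == "mRNA") "mRNA" else g$type
  rows <- list()
  add <- function(type, s0, e0, phase = ".", id = NULL, parent = NULL) {
    attrs <- if (dialect == "gff3") {
      gff3_attrs(id, parent)
    } else {
      paste0("gene_id \"", g$gene_id, "\"; transcript_id \"",
             t$transcript_id, "\";")
    }
    rows[[length(rows) + 1L]] <<- paste(chrom, "ribosim", type, s0 + 1L, e0,
                                        ".", t$strand, phase, attrs, sep = "\t")
  }

  if (dialect == "gff3") {
    add("gene", gspan[1], gspan[2], id = g$gene_id)
    add(tx_type, gspan[1], gspan[2], id = t$transcript_id, parent = g$gene_id)
  } else {
    add("gene", gspan[1], gspan[2])
    add("transcript", gspan[1], gspan[2])
  }
  for (j in seq_along(t$exon_start)) {
    add("exon", t$exon_start[j], t$exon_end[j],
        id = paste0(t$transcript_id, ".exon", j), parent = t$transcript_id)
  }
  if (g$type == "mRNA") {
    u5 <- g$u5; cds_len <- g$cds_len; tx_len <- g$tx_len
    emit_tx_interval <- function(type, a, b, with_phase = FALSE,
                                 tx_offset_for_phase = a) {
      if (b <= a) return(invisible())
      blocks <- tx_blocks(t, a, b)
      # phase is per-chunk in transcript order
      chunks <- list()
      for (i in seq_len(nrow(blocks))) {
        s0 <- blocks[i, 1]; e0 <- blocks[i, 2]
        tx_lo <- min(genomic_to_transcript(t, c(s0, e0 - 1L)))
        chunks[[length(chunks) + 1L]] <- c(s0, e0, tx_lo)
      }
      for (ch in chunks) {
        phase <- if (with_phase) {
          as.character((3L - (ch[3] - tx_offset_for_phase) %% 3L) %% 3L)
        } else "."
        add(type, ch[1], ch[2], phase = phase,
            id = paste0(t$transcript_id, ".", type),
            parent = t$transcript_id)
      }
    }
    emit_tx_interval("five_prime_UTR", 0L, u5)
    if (dialect == "gff3") {
      emit_tx_interval("CDS", u5, u5 + cds_len, with_phase = TRUE,
                       tx_offset_for_phase = u5)
    } else {
      emit_tx_interval("CDS", u5, u5 + cds_len - 3L, with_phase = TRUE,
                       tx_offset_for_phase = u5)
      emit_tx_interval("stop_codon", u5 + cds_len - 3L, u5 + cds_len)
    }
    emit_tx_interval("three_prime_UTR", u5 + cds_len, tx_len)
  }
  unlist(rows)
}

#' Simulate a miniature genome with annotation
#'
#' Generates one chromosome carrying `n_genes` protein-coding genes (ATG ...
#' TAA structure, UTRs, optionally multi-exon) plus rRNA and tRNA loci, and
#' writes the genome FASTA and a GFF3 annotation (optionally also a GTF
#' rendering of the same models). Deterministic given `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @param formats Annotation dialects to write: subset of `c("gff3", "gtf")`.
#' @return A `genome_sim` list with paths (`fasta`, `gff3`, `gtf`), the locus
#'   truth used by [simulate_reads()], and the genome sequence.
#' @export
simulate_genome <- function(spec, dir = tempfile("ribosim_"),
                            formats = c("gff3")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    cursor <- 0L
    loci <- list()
    seq_pieces <- character(0)
    push_spacer <- function() {
      w <- rint(spec$intergenic_range)
      seq_pieces[[length(seq_pieces) + 1L]] <<- random_dna(w)
      cursor <<- cursor + w
    }
    push_spacer()
    for (i in seq_len(spec$n_genes)) {
      g <- simulate_one_gene(spec, sprintf("g%02d", i), cursor)
      loci[[length(loci) + 1L]] <- g
      seq_pieces[[length(seq_pieces) + 1L]] <- g$seq
      cursor <- cursor + g$span
      push_spacer()
    }
    add_contaminant <- function(kind, n, len) {
      for (i in seq_len(n)) {
        gene_id <- sprintf("%s%02d", tolower(kind), i)
        strand <- sample(c("+", "-"), 1L)
        tx <- new_transcript_model(paste0(gene_id, ".t1"), spec$chrom_name,
                                   strand, cursor, cursor + len)
        loci[[length(loci) + 1L]] <<- list(gene_id = gene_id, type = kind,
                                           tx = tx, seq = random_dna(len),
                                           span = len)
        seq_pieces[[length(seq_pieces) + 1L]] <<- loci[[length(loci)]]$seq
        cursor <<- cursor + len
        push_spacer()
      }
    }
    add_contaminant("rRNA", spec$n_rrna, spec$rrna_length)
    add_contaminant("tRNA", spec$n_trna, spec$trna_length)

    genome <- Biostrings::DNAStringSet(setNames(paste(seq_pieces, collapse = ""),
                                                spec$chrom_name))
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)

    paths <- list(fasta = fasta, gff3 = NULL, gtf = NULL)
    for (fmt in formats) {
      rows <- unlist(lapply(loci, function(g) gene_annotation_rows(spec, g, fmt)))
      header <- if (fmt == "gff3") "##gff-version 3" else "#!gtf simulated"
      p <- file.path(dir, paste0("annotation.", fmt))
      writeLines(c(header, rows), p)
      paths[[fmt]] <- p
    }
    structure(list(fasta = paths$fasta, gff3 = paths$gff3, gtf = paths$gtf,
                   dir = dir, loci = loci, genome = genome, spec = spec),
              class = "genome_sim")
  })
}

sam_header <- function(gsim) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(gsim$genome),
            Biostrings::width(gsim$genome)))
}

read_seq_from_blocks <- function(chrom_seq, blocks) {
  paste(substring(chrom_seq, blocks[, 1] + 1L, blocks[, 2]), collapse = "")
}

blocks_to_cigar <- function(blocks) {
  if (nrow(blocks) == 1L) return(paste0(blocks[1, 2] - blocks[1, 1], "M"))
  parts <- character(0)
  for (i in seq_len(nrow(blocks))) {
    parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1], "M"))
    if (i < nrow(blocks)) {
      parts <- c(parts, paste0(blocks[i + 1, 1] - blocks[i, 2], "N"))
    }
  }
  paste(parts, collapse = "")
}

#' Simulate an aligned-read sample (BAM)
#'
#' Places footprints on a simulated genome so that the P-site (read 5' end
#' plus the true per-length offset, walked in spliced transcript space) lands
#' on codon starts with probability `in_frame`, splits the remainder evenly
#' over frames 1 and 2, adds start-codon pileup, rRNA/tRNA contamination, PCR
#' duplicates and a MAPQ uniqueness mix, then writes a coordinate-sorted,
#' indexed BAM. RNA-seq samples are placed uniformly along transcripts with
#' no frame structure.
#'
#' @param gsim A `genome_sim` from [simulate_genome()].
#' @param sample_name Sample label (also the BAM basename).
#' @param exp `"Ribo"` or `"RNA"`.
#' @param dir Output directory; defaults to the genome's.
#' @param n_reads Number of alignments; defaults to `spec$n_reads`.
#' @param seed Seed for this sample; defaults to `spec$seed + 1`.
#' @return Path to the sorted, indexed BAM file.
#' @export
simulate_reads <- function(gsim, sample_name, exp = c("Ribo", "RNA"),
                           dir = gsim$dir, n_reads = gsim$spec$n_reads,
                           seed = gsim$spec$seed + 1) {
  exp <- match.arg(exp)
  spec <- gsim$spec
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_seq <- as.character(gsim$genome[[1]])

  coding <- Filter(function(g) g$type == "mRNA", gsim$loci)
  rrna <- Filter(function(g) g$type == "rRNA", gsim$loci)
  trna <- Filter(function(g) g$type == "tRNA", gsim$loci)

  with_seed(seed, {
    n <- n_reads
    if (exp == "Ribo") {
      lens <- as.integer(sample(names(spec$length_probs), n, replace = TRUE,
                                prob = spec$length_probs))
      offs <- as.integer(spec$offsets[as.character(lens)])
      pr_r <- if (length(rrna)) spec$rrna_fraction else 0
      pr_t <- if (length(trna)) spec$trna_fraction else 0
      cat_draw <- stats::runif(n)
      category <- ifelse(cat_draw < pr_r, "rRNA",
                         ifelse(cat_draw < pr_r + pr_t, "tRNA", "gene"))
    } else {
      lens <- as.integer(sample(spec$rna_length_range[1]:spec$rna_length_range[2],
                                n, replace = TRUE))
      offs <- rep(0L, n)
      category <- rep("gene", n)
    }

    locus_idx <- integer(n)
    tpos5 <- integer(n)
    for (i in seq_len(n)) {
      if (category[i] == "gene") {
        g <- coding[[sample(length(coding), 1L)]]
        locus_idx[i] <- match(g$gene_id, vapply(gsim$loci, `[[`, "", "gene_id"))
        t <- g$tx
        if (exp == "Ribo") {
          n_codons <- (t$cds_stop_t - t$cds_start_t) %/% 3L
          codon <- if (stats::runif(1) < spec$start_pileup) 0L else
            sample(0:(n_codons - 1L), 1L)
          u <- stats::runif(1)
          shift <- if (u < spec$in_frame) 0L else
            if (u < spec$in_frame + (1 - spec$in_frame) / 2) 1L else 2L
          psite <- t$cds_start_t + 3L * codon + shift
          tpos5[i] <- psite - offs[i]
        } else {
          tpos5[i] <- sample(0:(t$length_t - lens[i]), 1L)
        }
      } else {
        pool <- if (category[i] == "rRNA") rrna else trna
        g <- pool[[sample(length(pool), 1L)]]
        locus_idx[i] <- match(g$gene_id, vapply(gsim$loci, `[[`, "", "gene_id"))
        tpos5[i] <- sample(0:(g$tx$length_t - lens[i]), 1L)
      }
    }

    rname <- rep(spec$chrom_name, n)
    pos1 <- integer(n)
    cigar <- character(n)
    seqs <- character(n)
    flag <- integer(n)
    for (i in seq_len(n)) {
      t <- gsim$loci[[locus_idx[i]]]$tx
      blocks <- tx_blocks(t, tpos5[i], tpos5[i] + lens[i])
      pos1[i] <- blocks[1, 1] + 1L
      cigar[i] <- blocks_to_cigar(blocks)
      seqs[i] <- read_seq_from_blocks(chrom_seq, blocks)
      flag[i] <- if (t$strand == "+") 0L else 16L
    }
    mapq <- ifelse(stats::runif(n) < spec$unique_frac, 50L, 1L)

    if (spec$duplication_rate > 0 && n > 1L) {
      dup <- stats::runif(n) < spec$duplication_rate
      dup[1L] <- FALSE
      if (any(dup)) {
        src <- sample(which(!dup), sum(dup), replace = TRUE)
        pos1[dup] <- pos1[src]; cigar[dup] <- cigar[src]
        seqs[dup] <- seqs[src]; flag[dup] <- flag[src]
        lens[dup] <- lens[src]; mapq[dup] <- mapq[src]
      }
    }

    qname <- sprintf("%s_r%06d", sample_name, seq_len(n))
    sam <- file.path(dir, paste0(sample_name, ".sam"))
    writeLines(c(sam_header(gsim),
                 paste(qname, flag, rname, pos1, mapq, cigar,
                       "*", 0L, 0L, seqs, "*", sep = "\t")),
               sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, sample_name),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    bam
  })
}

#' Build a synthetic reference QC-metric table
#'
#' Runs the full QC pipeline on several independently simulated good-quality
#' Ribo-seq samples and tabulates their per-sample summary metrics. The result
#' stands in for a curated reference dataset in reference-based anomaly
#' detection and is written as a plain TSV.
#'
#' @param spec A [sim_spec()] describing good-quality libraries.
#' @param n_samples Number of reference samples.
#' @param path Optional TSV output path.
#' @param configuration Opaque label stored with every row.
#' @return Tibble of summary rows (one per reference sample).
#' @export
reference_metrics_fixture <- function(spec = sim_spec(), n_samples = 6,
                                      path = NULL,
                                      configuration = "default") {
  gsim <- simulate_genome(spec)
  ann <- parse_annotation(gsim$gff3, gsim$fasta)
  rows <- lapply(seq_len(n_samples), function(i) {
    bam <- simulate_reads(gsim, sprintf("ref%02d", i), "Ribo",
                          seed = spec$seed + 100 + i)
    tab <- load_alignments(bam, sprintf("ref%02d", i), "Ribo")
    offs <- build_offset_table(tab, ann)
    ann_tab <- annotate_alignments(tab, ann, offs)
    summary_table(ann_tab)
  })
  out <- dplyr::bind_rows(rows)
  out$configuration <- configuration
  if (!is.null(path)) write_tsv_file(out, path)
  out
}
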