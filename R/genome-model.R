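#' Feature priority used when a position overlaps nested annotation records
#'
#' When a P-site overlaps several annotation records (a CDS nested in an exon
#' nested in an mRNA, say), the most specific label wins. Non-coding RNA
#' classes outrank protein-coding labels at the same position so that rRNA and
#' tRNA contamination stays visible in QC even where loci overlap mRNAs.
#' Feature types not in this list rank below `gene`.
#'
#' @return Character vector of feature labels, highest priority first.
#' @export
default_feature_priority <- function() {
  c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA", "ncRNA",
    "CDS", "five_prime_UTR", "three_prime_UTR",
    "exon", "mRNA", "transcript", "gene")
}

TX_LEVEL_TYPES <- c("mRNA", "transcript", "rRNA", "tRNA", "ncRNA",
                    "snoRNA", "snRNA", "miRNA", "lnc_RNA", "pseudogene")
TX_CHILD_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                    "five_prime_utr", "three_prime_utr", "UTR",
                    "start_codon", "stop_codon")

detect_annotation_dialect <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) return("GTF")
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) return("GFF3")
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) && grepl("gene_id \"", lines[[1]], fixed = TRUE)) "GTF" else "GFF3"
}

new_transcript_model <- function(transcript_id, chromosome, strand,
                                 exon_start, exon_end,
                                 cds_start_t = NA_integer_,
                                 cds_stop_t = NA_integer_) {
  ord <- order(exon_start)
  if (strand == "-") ord <- rev(ord)
  exon_start <- as.integer(exon_start[ord])
  exon_end <- as.integer(exon_end[ord])
  widths <- exon_end - exon_start
  stopifnot(all(widths > 0L))
  structure(list(
    transcript_id = transcript_id,
    chromosome = chromosome,
    strand = strand,
    exon_start = exon_start,
    exon_end = exon_end,
    cumbefore = as.integer(cumsum(c(0L, widths[-length(widths)]))),
    length_t = as.integer(sum(widths)),
    cds_start_t = as.integer(cds_start_t),
    cds_stop_t = as.integer(cds_stop_t)
  ), class = "TranscriptModel")
}

is_coding <- function(t) !is.na(t$cds_start_t)

cds_length <- function(t) {
  if (!is_coding(t)) return(0L)
  t$cds_stop_t + 3L - t$cds_start_t
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Coordinates are 0-based: transcript position 0 is the first (5'-most)
#' transcribed nucleotide. Positions falling in introns or outside the
#' transcript return `NA`.
#'
#' @param t A `TranscriptModel`.
#' @param gpos Integer vector of 0-based genomic positions.
#' @return Integer vector of 0-based transcript positions (`NA` when not exonic).
#' @export
genomic_to_transcript <- function(t, gpos) {
  tpos <- rep(NA_integer_, length(gpos))
  for (j in seq_along(t$exon_start)) {
    in_j <- !is.na(gpos) & gpos >= t$exon_start[j] & gpos < t$exon_end[j]
    if (!any(in_j)) next
    tpos[in_j] <- if (t$strand == "+") {
      t$cumbefore[j] + (gpos[in_j] - t$exon_start[j])
    } else {
      t$cumbefore[j] + (t$exon_end[j] - 1L - gpos[in_j])
    }
  }
  as.integer(tpos)
}

#' Map spliced transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on exonic positions.
#'
#' @param t A `TranscriptModel`.
#' @param tpos Integer vector of 0-based transcript positions.
#' @return Integer vector of 0-based genomic positions (`NA` when out of range).
#' @export
transcript_to_genomic <- function(t, tpos) {
  ok <- !is.na(tpos) & tpos >= 0L & tpos < t$length_t
  j <- rep(NA_integer_, length(tpos))
  j[ok] <- findInterval(tpos[ok], t$cumbefore)
  within <- tpos - t$cumbefore[j]
  gpos <- if (t$strand == "+") {
    t$exon_start[j] + within
  } else {
    t$exon_end[j] - 1L - within
  }
  gpos[!ok] <- NA_integer_
  as.integer(gpos)
}

#' Pick the major isoform of a gene
#'
#' Rule: the coding transcript with the longest CDS; ties broken by longest
#' spliced length, then by lexicographically smallest transcript id. Genes
#' without any coding transcript fall back to the longest transcript. The
#' choice is deterministic and independent of record order in the input file.
#'
#' @param gene A `GeneModel`.
#' @return Integer index into `gene$transcripts`.
#' @export
select_major_isoform <- function(gene) {
  txs <- gene$transcripts
  stopifnot(length(txs) >= 1L)
  cds_len <- vapply(txs, cds_length, integer(1))
  len_t <- vapply(txs, function(t) t$length_t, integer(1))
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  ord <- order(-cds_len, -len_t, ids)
  ord[[1L]]
}

resolve_gff3_records <- function(gr) {
  type <- as.character(gr$type)
  id <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  gene_rows <- which(type == "gene")
  gene_ids <- id[gene_rows]
  tx_rows <- which(!is.na(parent) & parent %in% gene_ids & type != "gene")
  tx_ids <- id[tx_rows]
  tx_gene <- parent[tx_rows]
  names(tx_gene) <- tx_ids
  child_rows <- which(!is.na(parent) & parent %in% tx_ids)

  list(
    type = type,
    gene_rows = gene_rows, gene_ids = gene_ids,
    tx_rows = tx_rows, tx_ids = tx_ids, tx_gene = tx_gene,
    child_rows = child_rows, child_tx = parent[child_rows],
    record_gene = {
      g <- rep(NA_character_, length(gr))
      g[gene_rows] <- gene_ids
      g[tx_rows] <- tx_gene
      g[child_rows] <- unname(tx_gene[parent[child_rows]])
      g
    }
  )
}

resolve_gtf_records <- function(gr) {
  type <- as.character(gr$type)
  gene_id <- as.character(gr$gene_id)
  tx_id <- as.character(gr$transcript_id %||% rep(NA_character_, length(gr)))
  tx_level <- !(type %in% c(TX_CHILD_TYPES, "gene")) & !is.na(tx_id)
  tx_rows <- which(tx_level)
  # one transcript-level record per transcript expected; keep first
  keep <- !duplicated(tx_id[tx_rows])
  tx_rows <- tx_rows[keep]
  child_rows <- which(type %in% TX_CHILD_TYPES & !is.na(tx_id))
  list(
    type = type,
    gene_rows = which(type == "gene"),
    gene_ids = unique(gene_id[c(tx_rows, child_rows)]),
    tx_rows = tx_rows, tx_ids = tx_id[tx_rows],
    tx_gene = setNames(gene_id[tx_rows], tx_id[tx_rows]),
    child_rows = child_rows, child_tx = tx_id[child_rows],
    record_gene = gene_id
  )
}

build_transcript <- function(gr, dialect, tx_row, tx_id, rows_of_tx, type) {
  chrom <- as.character(GenomicRanges::seqnames(gr))[tx_row]
  strand <- as.character(GenomicRanges::strand(gr))[tx_row]
  sub_type <- type[rows_of_tx]
  ex <- rows_of_tx[sub_type == "exon"]
  if (!length(ex)) ex <- tx_row  # transcripts without exon records span themselves
  # to 0-based half-open
  ex_start <- GenomicRanges::start(gr)[ex] - 1L
  ex_end <- GenomicRanges::end(gr)[ex]
  t <- new_transcript_model(tx_id, chrom, strand, ex_start, ex_end)

  cds_rows <- rows_of_tx[sub_type == "CDS"]
  stop_rows <- rows_of_tx[sub_type == "stop_codon"]
  if (length(cds_rows)) {
    span_rows <- c(cds_rows, stop_rows)
    g_lo <- GenomicRanges::start(gr)[span_rows] - 1L
    g_hi <- GenomicRanges::end(gr)[span_rows] - 1L
    tp <- genomic_to_transcript(t, c(g_lo, g_hi))
    if (anyNA(tp)) {
      stop("CDS record of transcript '", tx_id, "' falls outside its exons")
    }
    cds_lo <- min(tp)
    cds_hi <- max(tp) + 1L
    # GFF3 CDS spans include the stop codon; GTF CDS excludes it unless
    # stop_codon records were merged in above.
    cds_stop <- if (dialect == "GTF" && !length(stop_rows)) cds_hi else cds_hi - 3L
    if ((cds_stop - cds_lo) %% 3L != 0L) {
      warning("CDS length of transcript '", tx_id, "' is not a multiple of 3")
    }
    t$cds_start_t <- as.integer(cds_lo)
    t$cds_stop_t <- as.integer(cds_stop)
  }
  t
}

#' Parse a genome annotation and index it for QC
#'
#' Reads a GFF3 or GTF annotation (dialect auto-detected from the extension,
#' falling back to content sniffing), validates its chromosome names against
#' the FASTA genome, builds per-gene transcript models with spliced-coordinate
#' maps, selects each gene's major isoform, and constructs the
#' position-to-feature interval index used to label alignments.
#'
#' All internal coordinates are 0-based half-open; the 1-based inputs are
#' converted at this boundary.
#'
#' @param annotation_path Path to a GFF3 or GTF file.
#' @param fasta_path Path to the genome FASTA.
#' @param feature_priority Character vector ordering feature labels from most
#'   to least specific; see [default_feature_priority()].
#' @return A `GenomeAnnotation` object: named list of `GeneModel`s plus the
#'   feature interval index and cached major-isoform exon index.
#' @export
parse_annotation <- function(annotation_path, fasta_path,
                             feature_priority = default_feature_priority()) {
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dialect <- detect_annotation_dialect(annotation_path)
  gr <- tryCatch(
    rtracklayer::import(annotation_path, format = tolower(dialect)),
    error = function(e) {
      stop("failed to parse ", dialect, " file '", annotation_path, "': ",
           conditionMessage(e))
    })
  if (length(gr) == 0L) {
    stop("annotation file '", annotation_path, "' contains no records")
  }

  fasta_len <- Biostrings::fasta.seqlengths(fasta_path)
  names(fasta_len) <- sub("\\s.*", "", names(fasta_len))
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  missing <- setdiff(chroms, names(fasta_len))
  if (length(missing)) {
    stop("annotation chromosomes absent from FASTA: ",
         paste(missing, collapse = ", "))
  }

  res <- if (dialect == "GTF") resolve_gtf_records(gr) else resolve_gff3_records(gr)
  if (!length(res$tx_ids)) {
    stop("annotation file '", annotation_path, "' contains no transcripts")
  }

  children_by_tx <- split(res$child_rows, res$child_tx)
  genes <- list()
  for (g in sort(unique(unname(res$tx_gene)))) {
    tx_of_g <- res$tx_ids[res$tx_gene == g]
    tx_of_g <- sort(tx_of_g)
    txs <- lapply(tx_of_g, function(tid) {
      tx_row <- res$tx_rows[match(tid, res$tx_ids)]
      build_transcript(gr, dialect, tx_row, tid,
                       children_by_tx[[tid]] %||% integer(0), res$type)
    })
    gene <- structure(list(
      gene_id = g,
      chromosome = txs[[1]]$chromosome,
      strand = txs[[1]]$strand,
      transcripts = txs,
      major = NA_integer_
    ), class = "GeneModel")
    gene$major <- select_major_isoform(gene)
    genes[[g]] <- gene
  }

  feature <- res$type
  priority <- match(feature, feature_priority)
  priority[is.na(priority)] <- length(feature_priority) + 1L
  gene_of_rec <- res$record_gene
  gene_of_rec[is.na(gene_of_rec)] <- "Other"
  feature_gr <- GenomicRanges::granges(gr)
  S4Vectors::mcols(feature_gr) <- S4Vectors::DataFrame(
    feature = feature, gene_id = gene_of_rec, priority = priority)

  ann <- structure(list(
    genes = genes,
    feature_gr = feature_gr,
    feature_priority = feature_priority,
    source_dialect = dialect,
    chrom_lengths = fasta_len,
    fasta_path = fasta_path,
    annotation_path = annotation_path
  ), class = "GenomeAnnotation")
  ann$major_exons <- build_major_exon_index(ann)
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat("GenomeAnnotation (", x$source_dialect, "): ",
      length(x$genes), " genes, ", n_tx, " transcripts, ",
      length(x$feature_gr), " feature records\n", sep = "")
  invisible(x)
}

major_isoform <- function(ann, gene_id) {
  g <- ann$genes[[gene_id]]
  if (is.null(g)) return(NULL)
  g$transcripts[[g$major]]
}

build_major_exon_index <- function(ann) {
  rows <- lapply(ann$genes, function(g) {
    t <- g$transcripts[[g$major]]
    data.frame(
      chrom = t$chromosome, strand = t$strand,
      gstart0 = t$exon_start, gend0 = t$exon_end, cumbefore = t$cumbefore,
      gene_id = g$gene_id, transcript_id = t$transcript_id,
      length_t = t$length_t, cds_start_t = t$cds_start_t,
      cds_stop_t = t$cds_stop_t,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$gstart0 + 1L, df$gend0),
                               strand = df$strand)
  list(df = df, gr = gr)
}

# Vectorized lookup of 0-based genomic positions in major-isoform transcript
# space. Returns one row per input position; non-exonic positions get NA.
# When `gene` is supplied, hits are restricted to that gene per position.
map_to_major <- function(ann, chrom, strand, pos, gene = NULL) {
  n <- length(pos)
  out <- data.frame(
    gene_id = rep(NA_character_, n), transcript_id = NA_character_,
    tpos = NA_integer_, length_t = NA_integer_,
    cds_start_t = NA_integer_, cds_stop_t = NA_integer_,
    stringsAsFactors = FALSE)
  ok <- !is.na(pos) & !is.na(chrom)
  if (!any(ok)) return(out)
  q <- GenomicRanges::GRanges(chrom[ok],
                              IRanges::IRanges(pos[ok] + 1L, pos[ok] + 1L),
                              strand = strand[ok])
  fo <- GenomicRanges::findOverlaps(q, ann$major_exons$gr)
  if (!length(fo)) return(out)
  qi <- which(ok)[S4Vectors::queryHits(fo)]
  ri <- S4Vectors::subjectHits(fo)
  df <- ann$major_exons$df
  if (!is.null(gene)) {
    keep <- df$gene_id[ri] == gene[qi]
    qi <- qi[keep]; ri <- ri[keep]
  }
  if (!length(qi)) return(out)
  ord <- order(qi, df$gene_id[ri], ri)
  first <- !duplicated(qi[ord])
  qi <- qi[ord][first]; ri <- ri[ord][first]

  tpos <- ifelse(df$strand[ri] == "+",
                 df$cumbefore[ri] + (pos[qi] - df$gstart0[ri]),
                 df$cumbefore[ri] + (df$gend0[ri] - 1L - pos[qi]))
  out$gene_id[qi] <- df$gene_id[ri]
  out$transcript_id[qi] <- df$transcript_id[ri]
  out$tpos[qi] <- as.integer(tpos)
  out$length_t[qi] <- df$length_t[ri]
  out$cds_start_t[qi] <- df$cds_start_t[ri]
  out$cds_stop_t[qi] <- df$cds_stop_t[ri]
  out
}

#' Assign feature labels and gene ids to genomic positions
#'
#' Labels each (chromosome, strand, position) triple with the most specific
#' overlapping annotation record; positions overlapping nothing on the same
#' strand get `("Other", "Other")`. Ties at equal priority resolve to the
#' lexicographically smallest gene id.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param chromosome,strand,pos Parallel vectors (0-based positions).
#' @return A data.frame with columns `feature` and `gene_id`.
#' @export
assign_features <- function(annotation, chromosome, strand, pos) {
  n <- length(pos)
  out <- data.frame(feature = rep("Other", n), gene_id = rep("Other", n),
                    stringsAsFactors = FALSE)
  ok <- !is.na(pos) & !is.na(chromosome) &
    chromosome %in% GenomeInfoDb::seqlevels(annotation$feature_gr)
  if (!any(ok)) return(out)
  q <- GenomicRanges::GRanges(chromosome[ok],
                              IRanges::IRanges(pos[ok] + 1L, pos[ok] + 1L),
                              strand = strand[ok])
  fo <- GenomicRanges::findOverlaps(q, annotation$feature_gr)
  if (!length(fo)) return(out)
  qi <- which(ok)[S4Vectors::queryHits(fo)]
  ri <- S4Vectors::subjectHits(fo)
  mc <- S4Vectors::mcols(annotation$feature_gr)
  ord <- order(qi, mc$priority[ri], mc$gene_id[ri], ri)
  first <- !duplicated(qi[ord])
  qi <- qi[ord][first]; ri <- ri[ord][first]
  out$feature[qi] <- mc$feature[ri]
  out$gene_id[qi] <- mc$gene_id[ri]
  out
}

#' @rdname assign_features
#' @export
assign_feature <- function(annotation, chromosome, strand, pos) {
  res <- assign_features(annotation, chromosome, strand, pos)
  c(feature = res$feature[[1]], gene_id = res$gene_id[[1]])
}
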