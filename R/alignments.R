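ALIGNMENT_COLUMNS <- c("seqnames", "range_start", "range_end", "strand",
                       "sample", "exp", "length", "gc", "mapq")
ANNOTATION_COLUMNS <- c("pos", "gene", "feature", "start_dist", "end_dist",
                        "frame")

new_alignment_table <- function(df, provenance = list(), annotated = FALSE) {
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- provenance
  attr(out, "annotated") <- annotated
  class(out) <- unique(c("alignment_table", class(out)))
  out
}

#' Coerce a data frame to an alignment table
#'
#' For programmatic construction (e.g. tests or external import). The data
#' frame must carry the primary alignment columns (seqnames, range_start,
#' range_end, strand, sample, exp, length, gc, mapq); annotation columns are
#' recognised when present.
#'
#' @param df A data frame.
#' @return An `alignment_table`.
#' @export
as_alignment_table <- function(df) {
  missing <- setdiff(ALIGNMENT_COLUMNS, colnames(df))
  if (length(missing)) {
    stop("missing alignment column(s): ", paste(missing, collapse = ", "))
  }
  new_alignment_table(df, list(),
                      all(ANNOTATION_COLUMNS %in% colnames(df)))
}

#' GC content of read sequences
#'
#' Fraction of G and C bases; ambiguous bases (N) count in the denominator
#' only, so a read of all Ns has GC 0.
#'
#' @param read_sequence Character vector or `DNAStringSet` of read sequences.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
compute_gc <- function(read_sequence) {
  if (inherits(read_sequence, "XStringSet")) {
    w <- Biostrings::width(read_sequence)
    if (any(w == 0L)) stop("empty read sequence")
    return(as.vector(Biostrings::letterFrequency(read_sequence, "GC")) / w)
  }
  s <- toupper(as.character(read_sequence))
  n <- nchar(s)
  if (any(is.na(s)) || any(n == 0L)) stop("empty read sequence")
  gc <- nchar(gsub("[^GC]", "", s))
  gc / n
}

#' Classify alignments as uniquely mapped by MAPQ
#'
#' Alignments whose MAPQ equals the aligner's unique-mapping score (50 for
#' the default aligner convention) are unique; everything else is treated as
#' multi-mapping. The score is configurable for other aligners.
#'
#' @param mapq Integer vector of MAPQ scores.
#' @param unique_mapq The score denoting unique mapping (default 50).
#' @return Logical vector.
#' @export
classify_unique <- function(mapq, unique_mapq = 50L) {
  stopifnot(all(mapq >= 0L, na.rm = TRUE))
  !is.na(mapq) & mapq == unique_mapq
}

#' Load alignments from a BAM file
#'
#' Keeps primary, mapped, non-supplementary alignments (one record per
#' sequenced fragment); unmapped, secondary and supplementary records are
#' dropped and their count reported. Genomic coordinates are converted to
#' 0-based half-open at this boundary.
#'
#' @param bam_path Path to a BAM file (indexed, coordinate-sorted).
#' @param sample Sample label attached to every record.
#' @param exp Experiment type, `"Ribo"` or `"RNA"`.
#' @return An `alignment_table` tibble with columns seqnames, range_start,
#'   range_end, strand, sample, exp, length, gc, mapq.
#' @export
load_alignments <- function(bam_path, sample, exp = c("Ribo", "RNA")) {
  exp <- match.arg(exp)
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("seq", "mapq"))
  ga <- tryCatch(GenomicAlignments::readGAlignments(bam_path, param = param),
                 error = function(e) {
                   stop("failed to read BAM '", bam_path, "': ",
                        conditionMessage(e))
                 })
  total <- Rsamtools::countBam(bam_path)$records
  dropped <- total - length(ga)
  if (dropped > 0L) {
    message(dropped, " non-primary/unmapped record(s) dropped from ", bam_path)
  }
  prov <- setNames(list(list(path = bam_path, exp = exp, retained = length(ga),
                             dropped = dropped)), sample)
  if (length(ga) == 0L) {
    warning("BAM file '", bam_path, "' contains no usable alignments")
    df <- tibble::tibble(seqnames = character(0), range_start = integer(0),
                         range_end = integer(0), strand = character(0),
                         sample = character(0), exp = character(0),
                         length = integer(0), gc = numeric(0),
                         mapq = integer(0))
    return(new_alignment_table(df, prov))
  }
  mc <- S4Vectors::mcols(ga)
  df <- tibble::tibble(
    seqnames = as.character(GenomicAlignments::seqnames(ga)),
    range_start = GenomicAlignments::start(ga) - 1L,
    range_end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    sample = sample,
    exp = exp,
    length = GenomicAlignments::qwidth(ga),
    gc = compute_gc(mc$seq),
    mapq = as.integer(mc$mapq))
  new_alignment_table(df, prov)
}

#' Combine alignment tables from several samples
#'
#' @param ... `alignment_table` objects.
#' @return A single `alignment_table`.
#' @export
bind_alignments <- function(...) {
  tabs <- list(...)
  prov <- do.call(c, lapply(tabs, attr, "provenance"))
  annotated <- all(vapply(tabs, function(t) isTRUE(attr(t, "annotated")),
                          logical(1)))
  new_alignment_table(dplyr::bind_rows(tabs), prov, annotated)
}

lookup_offset <- function(offsets, lengths, fallback_offset = 12L) {
  if (is.null(offsets)) return(rep(as.integer(fallback_offset), length(lengths)))
  fb <- attr(offsets, "fallback_offset") %||% fallback_offset
  i <- match(lengths, offsets$length)
  out <- offsets$offset[i]
  out[is.na(out)] <- as.integer(fb)
  as.integer(out)
}

#' Attach the per-alignment attribute model
#'
#' Computes, for every alignment, the P-site-adjusted genomic position (read
#' 5' end shifted 3'-wards by the per-length offset, walked in spliced
#' transcript space when the 5' end lies in a major isoform, by a plain
#' genomic shift otherwise), the gene and most specific feature overlapping
#' that position on the same strand, and — when the P-site falls inside the
#' assigned gene's major isoform — the distance from the transcript 5' end
#' (`start_dist`), the distance to the first nucleotide of the stop codon
#' (`end_dist`) and the reading frame. Frame is `(transcript position -
#' cds_start) mod 3` against the start codon by default; `frame_anchor =
#' "tss"` anchors it at the transcript 5' end instead. Reads whose P-site is
#' intergenic get gene and feature `"Other"` with absent distances and frame.
#'
#' Re-annotating an annotated table with the same inputs is a no-op: every
#' derived column is recomputed from the primary coordinates.
#'
#' @param table An `alignment_table`.
#' @param annotation A `GenomeAnnotation`.
#' @param offsets An `OffsetTable` (or `NULL` to use `fallback_offset` for
#'   every Ribo-seq read; RNA-seq reads always use offset 0).
#' @param frame_anchor `"start_codon"` (default) or `"tss"`.
#' @param fallback_offset Offset for read lengths missing from `offsets`.
#' @return The table with columns pos, gene, feature, start_dist, end_dist,
#'   frame added (replaced if present).
#' @export
annotate_alignments <- function(table, annotation, offsets = NULL,
                                frame_anchor = c("start_codon", "tss"),
                                fallback_offset = 12L) {
  frame_anchor <- match.arg(frame_anchor)
  tab <- table[, setdiff(colnames(table), ANNOTATION_COLUMNS)]
  n <- nrow(tab)
  if (n == 0L) {
    tab$pos <- integer(0); tab$gene <- character(0); tab$feature <- character(0)
    tab$start_dist <- integer(0); tab$end_dist <- integer(0)
    tab$frame <- integer(0)
    return(new_alignment_table(tab, attr(table, "provenance"), TRUE))
  }

  five_end <- ifelse(tab$strand == "+", tab$range_start, tab$range_end - 1L)
  off <- ifelse(tab$exp == "Ribo",
                lookup_offset(offsets, tab$length, fallback_offset), 0L)

  m5 <- map_to_major(annotation, tab$seqnames, tab$strand, five_end)
  tpos_p <- m5$tpos + off
  spliced <- !is.na(tpos_p) & tpos_p >= 0L & tpos_p < m5$length_t
  pos <- ifelse(tab$strand == "+", five_end + off, five_end - off)
  if (any(spliced)) {
    for (g in unique(m5$gene_id[spliced])) {
      idx <- which(spliced & m5$gene_id == g)
      t <- major_isoform(annotation, g)
      pos[idx] <- transcript_to_genomic(t, tpos_p[idx])
    }
  }
  pos <- as.integer(pos)

  fg <- assign_features(annotation, tab$seqnames, tab$strand, pos)
  mp <- map_to_major(annotation, tab$seqnames, tab$strand, pos,
                     gene = fg$gene_id)
  coding <- !is.na(mp$cds_start_t)
  in_major <- !is.na(mp$tpos)
  frame <- rep(NA_integer_, n)
  idx <- which(in_major & coding)
  frame[idx] <- if (frame_anchor == "start_codon") {
    (mp$tpos[idx] - mp$cds_start_t[idx]) %% 3L
  } else {
    mp$tpos[idx] %% 3L
  }

  tab$pos <- pos
  tab$gene <- fg$gene_id
  tab$feature <- fg$feature
  tab$start_dist <- mp$tpos
  tab$end_dist <- ifelse(in_major & coding, mp$cds_stop_t - mp$tpos,
                         NA_integer_)
  tab$frame <- frame
  new_alignment_table(tab, attr(table, "provenance"), TRUE)
}

#' Filter and group an alignment table by its attributes
#'
#' `filters` is a named list over attribute columns; each element is either a
#' vector of allowed values or a predicate function on the column. `group_by`
#' names attribute columns whose value combinations partition the filtered
#' records. Groups are returned in deterministic (sorted-key) order, keyed by
#' the `|`-joined attribute values.
#'
#' @param table An `alignment_table`.
#' @param filters Named list of allowed-value vectors or predicate functions.
#' @param group_by Character vector of attribute names.
#' @return Named list of `alignment_table`s partitioning the filtered table.
#' @export
filter_and_group <- function(table, filters = list(),
                             group_by = character(0)) {
  bad <- setdiff(c(names(filters), group_by), colnames(table))
  if (length(bad)) {
    stop("unknown alignment attribute(s): ", paste(bad, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(table))
  for (col in names(filters)) {
    f <- filters[[col]]
    keep <- keep & if (is.function(f)) {
      isTRUE_v(f(table[[col]]))
    } else {
      table[[col]] %in% f
    }
  }
  filtered <- table[keep, ]
  if (!length(group_by)) {
    out <- list(all = new_alignment_table(filtered, attr(table, "provenance"),
                                          attr(table, "annotated")))
    return(out)
  }
  key <- do.call(paste, c(lapply(group_by, function(col) filtered[[col]]),
                          sep = "|"))
  keys <- sort(unique(key))
  out <- lapply(keys, function(k) {
    new_alignment_table(filtered[key == k, ], attr(table, "provenance"),
                        attr(table, "annotated"))
  })
  names(out) <- keys
  out
}

isTRUE_v <- function(x) {
  x[is.na(x)] <- FALSE
  as.logical(x)
}

#' Write an alignment table as TSV
#'
#' One column per alignment attribute, suitable for spreadsheet inspection or
#' re-import with [read_alignment_table()].
#'
#' @param table An `alignment_table`.
#' @param path Output path.
#' @export
write_alignment_table <- function(table, path) {
  write_tsv_file(as.data.frame(table), path)
}

#' @rdname write_alignment_table
#' @export
read_alignment_table <- function(path) {
  df <- read_tsv_file(path)
  new_alignment_table(df, list(), all(ANNOTATION_COLUMNS %in% colnames(df)))
}
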