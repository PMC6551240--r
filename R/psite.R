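#' Metagene read-density around translation starts for one read length
#'
#' Tallies unadjusted read 5' ends (strand-aware) of Ribo-seq reads of the
#' given length, positioned relative to the first nucleotide of the start
#' codon of each gene's major isoform, in spliced transcript coordinates.
#' Position 0 is the start-codon first nucleotide; negative positions are
#' upstream (5').
#'
#' @param table An `alignment_table` (annotation not required).
#' @param annotation A `GenomeAnnotation`.
#' @param length Read length (nt) to profile.
#' @param window `c(lo, hi)` relative window, `lo < 0 <= hi`.
#' @return Integer vector of counts named by relative position.
#' @export
start_anchored_density <- function(table, annotation, length,
                                   window = c(-40L, 20L)) {
  stopifnot(window[1] < 0L, window[2] >= 0L)
  positions <- window[1]:window[2]
  counts <- setNames(integer(base::length(positions)), positions)
  sub <- table[table$exp == "Ribo" & table$length == length, ]
  if (nrow(sub) == 0L) {
    warning("no Ribo-seq reads of length ", length)
    return(counts)
  }
  five_end <- ifelse(sub$strand == "+", sub$range_start, sub$range_end - 1L)
  m5 <- map_to_major(annotation, sub$seqnames, sub$strand, five_end)
  rel <- m5$tpos - m5$cds_start_t
  rel <- rel[!is.na(rel) & rel >= window[1] & rel <= window[2]]
  if (base::length(rel)) {
    tal <- table(factor(rel, levels = positions))
    counts <- setNames(as.integer(tal), positions)
  }
  counts
}

#' Infer the P-site offset for one read length
#'
#' The offset is the distance from the largest in-frame upstream peak of the
#' start-anchored 5'-end density to the translation start site. Because
#' ribosomes step in codons, the 5' ends of footprints of one length recur in
#' a single trinucleotide register; "in frame" means lying in that register.
#' Candidates are strictly upstream positions (p < 0) within one read length
#' of the start (so the P-site falls inside the read), restricted to the
#' register carrying the most upstream density; the offset is the distance of
#' the tallest candidate peak. Ties at equal height resolve to the smallest
#' offset. When fewer than `min_reads` reads support the window, or the
#' upstream density is empty, the canonical fallback offset is used and
#' flagged.
#'
#' @param density Named count vector from [start_anchored_density()].
#' @param length Read length (nt) the density describes.
#' @param min_reads Minimum reads in the window for inference.
#' @param fallback_offset Offset used when inference is unsupported.
#' @return List with `offset`, `n_reads`, `peak_pos`, `peak_height`,
#'   `fallback_used`.
#' @export
infer_offset <- function(density, length, min_reads = 50L,
                         fallback_offset = 12L) {
  positions <- as.integer(names(density))
  n_reads <- sum(density)
  up <- positions < 0L & -positions <= length
  fallback <- list(offset = as.integer(fallback_offset), n_reads = n_reads,
                   peak_pos = NA_integer_, peak_height = NA_integer_,
                   fallback_used = TRUE)
  if (n_reads < min_reads || !any(up) || all(density[up] == 0L)) {
    return(fallback)
  }
  reg_mass <- vapply(0:2, function(r) {
    sum(density[up & positions %% 3L == r])
  }, numeric(1))
  # tie between registers: prefer the one holding the tallest single peak,
  # then the one whose best peak is nearest the start
  best_of <- function(r) {
    cand <- up & positions %% 3L == r
    cp <- positions[cand]
    ch <- as.integer(density[cand])
    i <- order(-ch, -cp)[1]
    c(pos = cp[i], height = ch[i])
  }
  peaks <- vapply(0:2, best_of, c(pos = 0, height = 0))
  r_star <- order(-reg_mass, -peaks["height", ], peaks["pos", ] * -1)[1]
  best <- best_of(r_star - 1L)
  list(offset = as.integer(-best[["pos"]]), n_reads = n_reads,
       peak_pos = as.integer(best[["pos"]]),
       peak_height = as.integer(best[["height"]]), fallback_used = FALSE)
}

#' Build the per-length P-site offset table
#'
#' Runs [start_anchored_density()] and [infer_offset()] for every Ribo-seq
#' read length present in the sample (or an explicit set), collecting offsets
#' and diagnostics.
#'
#' @inheritParams start_anchored_density
#' @inheritParams infer_offset
#' @param lengths Integer vector of read lengths; defaults to all Ribo-seq
#'   lengths observed in `table`.
#' @return An `OffsetTable`: tibble with columns length, offset, n_reads,
#'   peak_pos, peak_height, fallback_used.
#' @export
build_offset_table <- function(table, annotation, lengths = NULL,
                               window = c(-40L, 20L), min_reads = 50L,
                               fallback_offset = 12L) {
  if (is.null(lengths)) {
    lengths <- sort(unique(table$length[table$exp == "Ribo"]))
  }
  if (!base::length(lengths)) {
    stop("no Ribo-seq reads present; cannot infer P-site offsets")
  }
  rows <- lapply(lengths, function(L) {
    dens <- suppressWarnings(start_anchored_density(table, annotation, L, window))
    res <- infer_offset(dens, L, min_reads, fallback_offset)
    tibble::tibble(length = as.integer(L), offset = res$offset,
                   n_reads = res$n_reads, peak_pos = res$peak_pos,
                   peak_height = res$peak_height,
                   fallback_used = res$fallback_used)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- window
  attr(out, "fallback_offset") <- as.integer(fallback_offset)
  attr(out, "min_reads") <- as.integer(min_reads)
  class(out) <- unique(c("OffsetTable", class(out)))
  out
}

#' Construct a fixed offset table
#'
#' For supplying known offsets (bypassing inference), e.g. from a previous
#' run or an external calibration.
#'
#' @param lengths Integer vector of read lengths.
#' @param offsets Integer vector of offsets, parallel to `lengths`.
#' @param fallback_offset Offset for lengths not listed.
#' @return An `OffsetTable`.
#' @export
offset_table <- function(lengths, offsets, fallback_offset = 12L) {
  stopifnot(base::length(lengths) == base::length(offsets),
            all(offsets >= 0L), all(offsets <= lengths))
  out <- tibble::tibble(length = as.integer(lengths),
                        offset = as.integer(offsets),
                        n_reads = NA_integer_, peak_pos = NA_integer_,
                        peak_height = NA_integer_, fallback_used = FALSE)
  attr(out, "fallback_offset") <- as.integer(fallback_offset)
  class(out) <- unique(c("OffsetTable", class(out)))
  out
}

#' Read and write offset tables
#'
#' The offset table is stored as a two-column TSV (length, offset); the
#' diagnostics (read support, peak location and height, fallback use) go to a
#' companion `<path>.diagnostics.tsv`.
#'
#' @param offsets An `OffsetTable`.
#' @param path TSV path.
#' @param fallback_offset Fallback recorded when reading a bare table.
#' @export
write_offset_table <- function(offsets, path) {
  write_tsv_file(as.data.frame(offsets[, c("length", "offset")]), path)
  write_tsv_file(as.data.frame(offsets), paste0(path, ".diagnostics.tsv"))
  invisible(path)
}

#' @rdname write_offset_table
#' @export
read_offset_table <- function(path, fallback_offset = 12L) {
  df <- read_tsv_file(path)
  stopifnot(all(c("length", "offset") %in% colnames(df)))
  offset_table(df$length, df$offset, fallback_offset)
}
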