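as_groups <- function(x) {
  if (inherits(x, "alignment_table") || is.data.frame(x)) list(all = x) else x
}

#' Read length distribution per group
#'
#' @param groups An `alignment_table` or a named list of them (from
#'   [filter_and_group()]).
#' @return Tibble with columns group, length, count, fraction; fractions sum
#'   to 1 within each nonempty group.
#' @export
read_length_distribution <- function(groups) {
  groups <- as_groups(groups)
  rows <- lapply(names(groups), function(k) {
    tab <- groups[[k]]
    if (nrow(tab) == 0L) return(NULL)
    cnt <- table(tab$length)
    tibble::tibble(group = k, length = as.integer(names(cnt)),
                   count = as.integer(cnt),
                   fraction = as.integer(cnt) / sum(cnt))
  })
  dplyr::bind_rows(rows)
}

#' GC-content distribution per group
#'
#' Histogram of per-read GC fractions.
#'
#' @inheritParams read_length_distribution
#' @param breaks Histogram bin boundaries over \[0, 1\].
#' @return Tibble with columns group, bin_lo, bin_hi, count, fraction.
#' @export
gc_distribution <- function(groups, breaks = seq(0, 1, by = 0.05)) {
  groups <- as_groups(groups)
  rows <- lapply(names(groups), function(k) {
    tab <- groups[[k]]
    if (nrow(tab) == 0L) {
      warning("group '", k, "' is empty; no GC distribution")
      return(NULL)
    }
    h <- graphics::hist(tab$gc, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    tibble::tibble(group = k, bin_lo = head(h$breaks, -1),
                   bin_hi = h$breaks[-1], count = h$counts,
                   fraction = h$counts / sum(h$counts))
  })
  dplyr::bind_rows(rows)
}

#' Percentage of alignments per feature (or any attribute) per group
#'
#' @inheritParams read_length_distribution
#' @param by Attribute column to tally (default `"feature"`).
#' @return Tibble with columns group, level, count, pct; pct sums to 100
#'   within each nonempty group.
#' @export
feature_percentages <- function(groups, by = "feature") {
  groups <- as_groups(groups)
  rows <- lapply(names(groups), function(k) {
    tab <- groups[[k]]
    if (nrow(tab) == 0L) return(NULL)
    if (!by %in% colnames(tab)) stop("unknown alignment attribute: ", by)
    cnt <- table(as.character(tab[[by]]), useNA = "no")
    tibble::tibble(group = k, level = names(cnt), count = as.integer(cnt),
                   pct = 100 * as.integer(cnt) / sum(cnt))
  })
  dplyr::bind_rows(rows)
}

#' Triplet periodicity: reading-frame fractions
#'
#' Fractions of CDS-mapped P-sites in frames 0, 1 and 2 relative to the start
#' codon. The frame-0 fraction is the headline periodicity metric of a
#' Ribo-seq library.
#'
#' @param table An annotated `alignment_table`.
#' @return Named numeric `c(f0, f1, f2)` summing to 1, with attribute
#'   `n_reads` (number of frame-assigned records).
#' @export
frame_periodicity <- function(table) {
  fr <- table$frame[!is.na(table$frame)]
  n <- length(fr)
  if (n == 0L) {
    warning("no frame-assigned reads; periodicity undefined")
    out <- c(f0 = NA_real_, f1 = NA_real_, f2 = NA_real_)
    attr(out, "n_reads") <- 0L
    return(out)
  }
  out <- c(f0 = mean(fr == 0L), f1 = mean(fr == 1L), f2 = mean(fr == 2L))
  attr(out, "n_reads") <- n
  out
}

#' Metagene profile of P-site density around translation start or stop
#'
#' Aggregates P-site-adjusted positions across all major isoforms, relative
#' to the first nucleotide of the start codon (`anchor = "start"`) or of the
#' stop codon (`anchor = "stop"`). Optionally subsamples alignments uniformly
#' without replacement under a fixed seed before counting, which large
#' libraries use to bound compute.
#'
#' @param table An annotated `alignment_table`.
#' @param annotation A `GenomeAnnotation`.
#' @param anchor `"start"` or `"stop"`.
#' @param window `c(lo, hi)` relative window in nt.
#' @param group_by Optional attribute columns; one profile per combination.
#' @param subsample Optional number of alignments to draw (ignored when the
#'   table is no larger).
#' @param seed Seed for subsampling.
#' @param normalize If `TRUE` add a fraction column summing to 1 per group.
#' @return Tibble with columns group, anchor, position, count (and fraction).
#' @export
metagene_profile <- function(table, annotation, anchor = c("start", "stop"),
                             window = c(-50L, 50L), group_by = NULL,
                             subsample = NULL, seed = 1L, normalize = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(isTRUE(attr(table, "annotated")))
  if (!is.null(subsample) && subsample < nrow(table)) {
    idx <- with_seed(seed, sample.int(nrow(table), subsample))
    table <- table[sort(idx), ]
  }
  mp <- map_to_major(annotation, table$seqnames, table$strand, table$pos,
                     gene = table$gene)
  anchor_t <- if (anchor == "start") mp$cds_start_t else mp$cds_stop_t
  rel <- mp$tpos - anchor_t
  key <- if (is.null(group_by)) rep("all", nrow(table)) else {
    do.call(paste, c(lapply(group_by, function(col) table[[col]]), sep = "|"))
  }
  positions <- window[1]:window[2]
  ok <- !is.na(rel) & rel >= window[1] & rel <= window[2]
  rows <- lapply(sort(unique(key)), function(k) {
    sel <- ok & key == k
    cnt <- as.integer(table(factor(rel[sel], levels = positions)))
    out <- tibble::tibble(group = k, anchor = anchor, position = positions,
                          count = cnt)
    if (normalize) {
      out$fraction <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, length(cnt))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Library complexity and duplication
#'
#' Complexity is the fraction of distinct alignment tuples (chromosome,
#' strand, start, read length) among all alignments; duplication is its
#' complement. Both are computable from the BAM alone and proxy for library
#' diversity.
#'
#' @param table An `alignment_table` (one sample).
#' @return Fraction in (0, 1\].
#' @export
complexity <- function(table) {
  n <- nrow(table)
  if (n == 0L) {
    warning("empty alignment table; complexity undefined")
    return(NA_real_)
  }
  key <- paste(table$seqnames, table$strand, table$range_start, table$length,
               sep = "\r")
  length(unique(key)) / n
}

#' @rdname complexity
#' @export
duplication <- function(table) 1 - complexity(table)

#' RPKM per gene
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (total_mapped * gene_length)`. Gene length is the spliced
#' length of the gene's major isoform; a read counts toward the gene its
#' P-site-adjusted position was assigned to (for RNA-seq the offset is 0, so
#' this is the 5' end).
#'
#' @param table An annotated `alignment_table`.
#' @param annotation A `GenomeAnnotation`.
#' @return Tibble with columns sample, exp, gene, count, length_nt, rpkm
#'   covering every annotated gene in every sample.
#' @export
rpkm <- function(table, annotation) {
  stopifnot(isTRUE(attr(table, "annotated")))
  gene_len <- vapply(annotation$genes,
                     function(g) g$transcripts[[g$major]]$length_t, integer(1))
  samples <- unique(table$sample)
  rows <- lapply(samples, function(s) {
    sub <- table[table$sample == s, ]
    total <- nrow(sub)
    cnt <- table(factor(sub$gene, levels = names(gene_len)))
    tibble::tibble(sample = s, exp = sub$exp[1], gene = names(gene_len),
                   count = as.integer(cnt), length_nt = unname(gene_len),
                   rpkm = if (total > 0) {
                     as.integer(cnt) * 1e9 / (total * unname(gene_len))
                   } else rep(0, length(gene_len)))
  })
  dplyr::bind_rows(rows)
}

#' Translational efficiency per gene
#'
#' Ratio of Ribo-seq to RNA-seq RPKM, optionally stabilised by a pseudocount
#' added to both: `TE = (ribo + pc) / (rna + pc)`. With pseudocount 0 and RNA
#' RPKM 0 the ratio is undefined; such genes get `NA` and are flagged.
#'
#' @param ribo_rpkm,rna_rpkm Tibbles from [rpkm()] (single sample each) or
#'   named numeric vectors of RPKM by gene.
#' @param pseudocount Non-negative stabiliser (default 0).
#' @return Tibble with columns gene, ribo_rpkm, rna_rpkm, te, undefined.
#' @export
translational_efficiency <- function(ribo_rpkm, rna_rpkm, pseudocount = 0) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$rpkm, x$gene) else x
  }
  r <- as_vec(ribo_rpkm)
  m <- as_vec(rna_rpkm)
  genes <- intersect(names(r), names(m))
  r <- r[genes]; m <- m[genes]
  denom <- m + pseudocount
  te <- ifelse(denom > 0, (r + pseudocount) / denom, NA_real_)
  tibble::tibble(gene = genes, ribo_rpkm = unname(r), rna_rpkm = unname(m),
                 te = unname(te), undefined = denom == 0)
}

#' Per-sample QC summary table
#'
#' One row per sample: total alignments, percent uniquely mapped, feature
#' percentages (columns `pct_<feature>`), library complexity and duplication,
#' reading-frame fractions f0/f1/f2 and the headline periodicity (= f0).
#' Periodicity columns are computed for RNA-seq samples too but are only
#' biologically meaningful for Ribo-seq; consult the `exp` column.
#'
#' @param table An annotated `alignment_table` (any number of samples).
#' @param unique_mapq MAPQ score denoting unique mapping.
#' @return Tibble, one row per sample.
#' @export
summary_table <- function(table, unique_mapq = 50L) {
  stopifnot(isTRUE(attr(table, "annotated")))
  features <- sort(unique(table$feature))
  rows <- lapply(sort(unique(table$sample)), function(s) {
    sub <- table[table$sample == s, ]
    fr <- suppressWarnings(frame_periodicity(sub))
    fp <- 100 * as.integer(table(factor(sub$feature, levels = features))) /
      nrow(sub)
    row <- tibble::tibble(
      sample = s, exp = sub$exp[1],
      total_alignments = nrow(sub),
      pct_unique = 100 * mean(classify_unique(sub$mapq, unique_mapq)),
      complexity = complexity(sub),
      duplication = duplication(sub),
      f0 = fr[["f0"]], f1 = fr[["f1"]], f2 = fr[["f2"]],
      periodicity = fr[["f0"]])
    for (i in seq_along(features)) {
      row[[paste0("pct_", features[i])]] <- fp[i]
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Export P-site coverage of one gene as bedGraph
#'
#' Per-position P-site counts over the gene's genomic span, for browser-style
#' inspection of a single gene.
#'
#' @param table An annotated `alignment_table`.
#' @param annotation A `GenomeAnnotation`.
#' @param gene_id Gene to export.
#' @param path Optional output path; when given, a bedGraph file is written.
#' @return Tibble with columns chrom, start, end, count (0-based half-open).
#' @export
gene_coverage <- function(table, annotation, gene_id, path = NULL) {
  g <- annotation$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene: ", gene_id)
  t <- g$transcripts[[g$major]]
  span <- c(min(t$exon_start), max(t$exon_end))
  sub <- table[table$gene == gene_id & !is.na(table$pos), ]
  cnt <- table(factor(sub$pos, levels = span[1]:(span[2] - 1L)))
  keep <- as.integer(cnt) > 0L
  out <- tibble::tibble(chrom = g$chromosome,
                        start = (span[1]:(span[2] - 1L))[keep],
                        end = (span[1]:(span[2] - 1L))[keep] + 1L,
                        count = as.integer(cnt)[keep])
  if (!is.null(path)) {
    writeLines(c(sprintf("track type=bedGraph name=\"%s\"", gene_id),
                 paste(out$chrom, out$start, out$end, out$count, sep = "\t")),
               path)
  }
  out
}
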