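# Independent brute-force oracles, kept deliberately naive.

# Genomic positions of a transcript enumerated base by base, 5' -> 3'.
enumerate_tx_positions <- function(t) {
  unlist(lapply(seq_along(t$exon_start), function(j) {
    if (t$strand == "+") t$exon_start[j]:(t$exon_end[j] - 1L)
    else (t$exon_end[j] - 1L):t$exon_start[j]
  }))
}

bf_genomic_to_transcript <- function(t, gpos) {
  walk <- enumerate_tx_positions(t)
  match(gpos, walk) - 1L
}

bf_frame <- function(t, gpos) {
  tp <- bf_genomic_to_transcript(t, gpos)
  if (is.na(tp) || is.na(t$cds_start_t)) return(NA_integer_)
  (tp - t$cds_start_t) %% 3L
}

# Tukey's fence by explicit sorted-quartile interpolation (type 7).
bf_tukey_outliers <- function(x, k = 1.5) {
  s <- sort(x)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- interp(0.25); q3 <- interp(0.75)
  iqr <- q3 - q1
  x < q1 - k * iqr | x > q3 + k * iqr
}

# Feature assignment by scanning every annotation record.
bf_assign_feature <- function(records, priority, chrom, strand, pos) {
  hit <- records$seqid == chrom & records$strand == strand &
    records$start - 1L <= pos & pos < records$end
  if (!any(hit)) return(c(feature = "Other", gene_id = "Other"))
  sub <- records[hit, ]
  pr <- match(sub$type, priority)
  pr[is.na(pr)] <- length(priority) + 1L
  best <- order(pr, sub$gene_id)[1]
  c(feature = sub$type[best], gene_id = sub$gene_id[best])
}

# Random multi-exon transcript models for property tests (no file I/O).
random_transcript <- function(strand = "+", n_exons = 3L, coding = TRUE) {
  widths <- sample(20:80, n_exons, replace = TRUE)
  gaps <- sample(30:100, n_exons, replace = TRUE)
  starts <- cumsum(gaps + c(0, widths[-n_exons])) + 100L
  ends <- starts + widths
  len <- sum(widths)
  cds_start <- if (coding) sample(0:(len %/% 3), 1L) else NA_integer_
  cds_stop <- if (coding) {
    ncod <- (len - cds_start - 3L) %/% 3L
    cds_start + 3L * max(1L, sample(seq_len(max(1L, ncod)), 1L))
  } else NA_integer_
  riboqc:::new_transcript_model(
    sprintf("rt_%s", paste(sample(letters, 6), collapse = "")),
    "chrR", strand, starts, ends, cds_start, cds_stop)
}
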