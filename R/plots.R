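#' QC plots
#'
#' Standard ggplot2 renderings of the QC tables: read-length distribution,
#' GC-content distribution, feature percentages, metagene profiles and
#' reading-frame periodicity bars.
#'
#' @param x The corresponding QC tibble ([read_length_distribution()],
#'   [gc_distribution()], [feature_percentages()], [metagene_profile()],
#'   [summary_table()]).
#' @return A ggplot object.
#' @name qc_plots
NULL

#' @rdname qc_plots
#' @export
plot_read_length_distribution <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$length), y = .data$fraction,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_gc_distribution <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$fraction, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "GC fraction", y = "fraction of reads", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_feature_percentages <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$group, y = .data$pct,
                                  fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of alignments", fill = "feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname qc_plots
#' @export
plot_metagene_profile <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$position, y = .data$count,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~anchor, scales = "free_y") +
    ggplot2::labs(x = "position relative to anchor (nt)", y = "P-site count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_frame_periodicity <- function(x) {
  long <- tibble::tibble(
    sample = rep(x$sample, 3),
    frame = rep(c("0", "1", "2"), each = nrow(x)),
    fraction = c(x$f0, x$f1, x$f2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                     fill = .data$frame)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of CDS P-sites", fill = "frame") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

save_plot <- function(p, path_stem, width = 6, height = 4) {
  written <- character(0)
  for (ext in c("png", "pdf")) {
    f <- paste0(path_stem, ".", ext)
    ok <- tryCatch({
      suppressMessages(ggplot2::ggsave(f, p, width = width, height = height,
                                       dpi = 96))
      TRUE
    }, error = function(e) {
      warning("could not write ", f, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) written <- c(written, f)
  }
  written
}
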