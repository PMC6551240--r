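html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 25L) {
  truncated <- nrow(df) > max_rows
  shown <- head(df, max_rows)
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) v <- signif(v, 5)
    html_escape(as.character(v))
  }
  header <- paste0("<tr>", paste0("<th>", html_escape(colnames(shown)),
                                  "</th>", collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(shown)), function(i) {
    cells <- vapply(shown[i, ], function(v) fmt(v[[1]]), character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  note <- if (truncated) {
    sprintf("<p class='note'>showing %d of %d rows</p>", max_rows, nrow(df))
  } else ""
  paste0("<table>", header, paste(body, collapse = "\n"), "</table>", note)
}

embed_png <- function(path) {
  if (!file.exists(path)) return("")
  raw <- readBin(path, "raw", file.size(path))
  sprintf("<img src=\"data:image/png;base64,%s\" style=\"max-width:48em\"/>",
          jsonlite::base64_enc(raw))
}

TOOL_SECTIONS <- list(
  offsets = list(title = "P-site offsets",
                 blurb = "Per read length: offset from the read 5' end to the P-site, inferred from the largest in-frame upstream peak of the start-anchored metagene density, with diagnostics.",
                 table = "offsets", plot = NULL),
  summary = list(title = "Summary table",
                 blurb = "Per-sample totals, percent uniquely mapped, feature percentages, library complexity/duplication and reading-frame periodicity.",
                 table = "summary", plot = NULL),
  read_length = list(title = "Read length distribution",
                     blurb = "Distribution of aligned read lengths per sample.",
                     table = "read_length", plot = "read_length.png"),
  gc = list(title = "GC content", blurb = "Per-read GC fraction histograms.",
            table = "gc", plot = "gc.png"),
  feature = list(title = "Feature percentages",
                 blurb = "Share of alignments per annotation feature type.",
                 table = "feature", plot = "feature_pct.png"),
  frame = list(title = "Reading-frame periodicity",
               blurb = "Fraction of CDS-mapped P-sites in each frame relative to the start codon.",
               table = "frame", plot = "frame.png"),
  metagene = list(title = "Metagene profiles",
                  blurb = "P-site density around translation start and stop, aggregated over major isoforms.",
                  table = "metagene", plot = "metagene.png"),
  rpkm = list(title = "RPKM", blurb = "Reads per kilobase of major-isoform transcript per million mapped reads.",
              table = "rpkm", plot = NULL),
  te = list(title = "Translational efficiency",
            blurb = "Ratio of Ribo-seq to RNA-seq RPKM per gene.",
            table = "te", plot = NULL),
  anomaly = list(title = "Anomaly detection",
                 blurb = "Per-sample, per-metric verdicts from expert thresholds, Tukey's fence across samples, percent error against controls, and reference fences.",
                 table = "anomaly", plot = NULL)
)

#' Generate a self-contained HTML report
#'
#' Combines the outputs of the selected tools, the full parameter echo and
#' optional user notes into a single HTML document with embedded figures.
#' Section order follows the tool order of the configuration; the notes
#' section is omitted when notes are empty.
#'
#' @param bundle A `qc_bundle` from [run_pipeline()].
#' @param config The run configuration (defaults to the bundle's).
#' @param notes Free text included verbatim (escaped) in the report.
#' @param path Output path (default `report.html` in the bundle directory).
#' @return The report path, invisibly.
#' @export
generate_report <- function(bundle, config = bundle$config,
                            notes = config$notes,
                            path = file.path(bundle$out_dir, "report.html")) {
  sections <- character(0)
  for (tool in config$tools) {
    sec <- TOOL_SECTIONS[[tool]]
    if (is.null(sec)) next
    tab <- bundle$tables[[sec$table]]
    if (is.null(tab)) next
    parts <- c(sprintf("<h2>%s</h2>", sec$title),
               sprintf("<p>%s</p>", sec$blurb))
    if (!is.null(sec$plot)) {
      parts <- c(parts, embed_png(file.path(bundle$out_dir, sec$plot)))
    }
    parts <- c(parts, html_table(as.data.frame(tab)))
    sections <- c(sections, paste(parts, collapse = "\n"))
  }
  notes_html <- if (nzchar(trimws(notes %||% ""))) {
    sprintf("<h2>Notes</h2>\n<p>%s</p>", html_escape(notes))
  } else ""
  params <- sprintf("<h2>Parameters</h2>\n<pre>%s</pre>",
                    html_escape(as.character(config_json(config))))
  html <- paste(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Ribo-seq QC report</title>",
    "<style>body{font-family:sans-serif;margin:2em;max-width:60em}",
    "table{border-collapse:collapse;font-size:0.85em}",
    "td,th{border:1px solid #999;padding:2px 6px}",
    ".note{color:#666;font-size:0.8em}</style></head><body>",
    "<h1>Ribo-seq quality-control report</h1>",
    paste(sections, collapse = "\n"),
    notes_html,
    params,
    "</body></html>",
    sep = "\n")
  writeLines(html, path)
  invisible(path)
}
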