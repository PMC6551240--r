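PIPELINE_TOOLS <- c("offsets", "summary", "read_length", "gc", "feature",
                    "frame", "metagene", "rpkm", "te", "anomaly")

#' Assemble a pipeline run configuration
#'
#' All analysis parameters in one serializable object. Re-running the
#' pipeline with the same configuration and inputs reproduces every table
#' bit-for-bit.
#'
#' @param samples Data frame with columns `bam`, `sample`, `exp`
#'   (`"Ribo"`/`"RNA"`).
#' @param annotation Path to the GFF3/GTF annotation.
#' @param fasta Path to the genome FASTA.
#' @param out_dir Output directory.
#' @param tools Which tool outputs to produce (subset of
#'   `r paste(PIPELINE_TOOLS, collapse = ", ")`).
#' @param offsets_path Optional fixed offset-table TSV; bypasses inference.
#' @param start_window Window around the start codon for offset inference.
#' @param metagene_window Window for metagene profiles.
#' @param min_reads Minimum read support per length for offset inference.
#' @param fallback_offset Fallback P-site offset (nt).
#' @param subsample Optional metagene subsample size.
#' @param seed Seed for every stochastic step.
#' @param unique_mapq MAPQ score treated as uniquely mapped.
#' @param frame_anchor `"start_codon"` or `"tss"`.
#' @param thresholds Expert anomaly thresholds (NULL disables the strategy).
#' @param controls Control sample names (NULL disables the strategy).
#' @param reference Reference metric table TSV path (NULL disables).
#' @param te_pairs Optional data frame with columns `ribo`, `rna` naming
#'   matched samples for translational efficiency; defaults to the single
#'   Ribo/RNA pair when unambiguous.
#' @param notes Free-text notes embedded in the report.
#' @return A `run_config` list.
#' @export
run_config <- function(samples, annotation, fasta, out_dir,
                       tools = PIPELINE_TOOLS,
                       offsets_path = NULL,
                       start_window = c(-40L, 20L),
                       metagene_window = c(-50L, 50L),
                       min_reads = 50L, fallback_offset = 12L,
                       subsample = NULL, seed = 1L, unique_mapq = 50L,
                       frame_anchor = "start_codon",
                       thresholds = default_expert_thresholds(),
                       controls = NULL, reference = NULL, te_pairs = NULL,
                       notes = "") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("bam", "sample", "exp") %in% colnames(samples)),
            all(samples$exp %in% c("Ribo", "RNA")),
            !anyDuplicated(samples$sample),
            all(tools %in% PIPELINE_TOOLS))
  structure(list(samples = samples, annotation = annotation, fasta = fasta,
                 out_dir = out_dir, tools = tools, offsets_path = offsets_path,
                 start_window = as.integer(start_window),
                 metagene_window = as.integer(metagene_window),
                 min_reads = as.integer(min_reads),
                 fallback_offset = as.integer(fallback_offset),
                 subsample = subsample, seed = as.integer(seed),
                 unique_mapq = as.integer(unique_mapq),
                 frame_anchor = frame_anchor, thresholds = thresholds,
                 controls = controls, reference = reference,
                 te_pairs = te_pairs, notes = notes),
            class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                   pretty = TRUE, digits = NA)
}

validate_config <- function(config) {
  paths <- c(config$samples$bam, config$annotation, config$fasta,
             config$offsets_path,
             if (is.character(config$reference)) config$reference)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the QC pipeline
#'
#' Executes annotation parsing, alignment loading, per-sample P-site offset
#' inference, attribute annotation, the selected QC tools and anomaly
#' detection, writing every table (TSV), plot (PNG + PDF) and a JSON manifest
#' with per-file checksums under `config$out_dir`. Inputs are validated
#' before any compute; a failing stage raises an error naming the stage with
#' partial outputs preserved on disk.
#'
#' @param config A [run_config()].
#' @return Invisibly, the output bundle: the configuration, every computed
#'   table, the annotated alignment table and the manifest.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  timings <- list()
  tables <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_file(as.data.frame(df), p)
    files <<- c(files, p)
    p
  }
  emit_plot <- function(p, stem) {
    files <<- c(files, save_plot(p, file.path(config$out_dir, stem)))
  }

  ann <- stage("parse_annotation",
               parse_annotation(config$annotation, config$fasta))

  tabs <- stage("load_alignments", {
    lapply(seq_len(nrow(config$samples)), function(i) {
      load_alignments(config$samples$bam[i], config$samples$sample[i],
                      config$samples$exp[i])
    })
  })

  fixed_offsets <- if (!is.null(config$offsets_path)) {
    read_offset_table(config$offsets_path, config$fallback_offset)
  } else NULL

  annotated <- list()
  offset_rows <- list()
  stage("offsets_and_annotation", {
    for (i in seq_along(tabs)) {
      tab <- tabs[[i]]
      offs <- fixed_offsets
      if (is.null(offs) && config$samples$exp[i] == "Ribo" && nrow(tab) > 0) {
        offs <- build_offset_table(tab, ann, window = config$start_window,
                                   min_reads = config$min_reads,
                                   fallback_offset = config$fallback_offset)
        o <- as.data.frame(offs)
        o$sample <- config$samples$sample[i]
        offset_rows[[length(offset_rows) + 1L]] <- o
      }
      annotated[[i]] <- annotate_alignments(tab, ann, offs,
                                             config$frame_anchor,
                                             config$fallback_offset)
    }
  })
  table_all <- do.call(bind_alignments, annotated)
  tables$alignments <- table_all
  emit(table_all, "alignments.tsv")

  if ("offsets" %in% config$tools && length(offset_rows)) {
    tables$offsets <- dplyr::bind_rows(offset_rows)
    emit(tables$offsets, "offsets.tsv")
  }

  summary <- stage("summary", summary_table(table_all, config$unique_mapq))
  if ("summary" %in% config$tools) {
    tables$summary <- summary
    emit(summary, "summary.tsv")
  }

  groups <- filter_and_group(table_all, group_by = "sample")
  if ("read_length" %in% config$tools) {
    stage("read_length", {
      tables$read_length <- read_length_distribution(groups)
      emit(tables$read_length, "read_length.tsv")
      emit_plot(plot_read_length_distribution(tables$read_length),
                "read_length")
    })
  }
  if ("gc" %in% config$tools) {
    stage("gc", {
      tables$gc <- gc_distribution(groups)
      emit(tables$gc, "gc.tsv")
      emit_plot(plot_gc_distribution(tables$gc), "gc")
    })
  }
  if ("feature" %in% config$tools) {
    stage("feature", {
      tables$feature <- feature_percentages(groups)
      emit(tables$feature, "feature_pct.tsv")
      emit_plot(plot_feature_percentages(tables$feature), "feature_pct")
    })
  }
  if ("frame" %in% config$tools) {
    stage("frame", {
      tables$frame <- feature_percentages(groups, by = "frame")
      emit(tables$frame, "frame_pct.tsv")
      emit_plot(plot_frame_periodicity(summary), "frame")
    })
  }
  if ("metagene" %in% config$tools) {
    stage("metagene", {
      mg <- dplyr::bind_rows(
        metagene_profile(table_all, ann, "start", config$metagene_window,
                         group_by = "sample", subsample = config$subsample,
                         seed = config$seed),
        metagene_profile(table_all, ann, "stop", config$metagene_window,
                         group_by = "sample", subsample = config$subsample,
                         seed = config$seed))
      tables$metagene <- mg
      emit(mg, "metagene.tsv")
      emit_plot(plot_metagene_profile(mg), "metagene")
    })
  }
  if ("rpkm" %in% config$tools || "te" %in% config$tools) {
    stage("rpkm", {
      tables$rpkm <- rpkm(table_all, ann)
      if ("rpkm" %in% config$tools) emit(tables$rpkm, "rpkm.tsv")
    })
  }
  if ("te" %in% config$tools) {
    stage("te", {
      pairs <- config$te_pairs
      if (is.null(pairs)) {
        ribo <- config$samples$sample[config$samples$exp == "Ribo"]
        rna <- config$samples$sample[config$samples$exp == "RNA"]
        if (length(ribo) == 1L && length(rna) == 1L) {
          pairs <- data.frame(ribo = ribo, rna = rna)
        }
      }
      if (!is.null(pairs) && nrow(pairs)) {
        te <- lapply(seq_len(nrow(pairs)), function(i) {
          out <- translational_efficiency(
            tables$rpkm[tables$rpkm$sample == pairs$ribo[i], ],
            tables$rpkm[tables$rpkm$sample == pairs$rna[i], ])
          out$ribo_sample <- pairs$ribo[i]
          out$rna_sample <- pairs$rna[i]
          out
        })
        tables$te <- dplyr::bind_rows(te)
        emit(tables$te, "te.tsv")
      } else {
        message("no unambiguous Ribo/RNA pairing; translational efficiency skipped")
      }
    })
  }
  if ("anomaly" %in% config$tools) {
    stage("anomaly", {
      tables$anomaly <- detect_anomalies(summary,
                                          thresholds = config$thresholds,
                                          controls = config$controls,
                                          reference = config$reference)
      emit(tables$anomaly, "anomaly.tsv")
    })
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(config_json(config), cfg_path)
  files <- c(files, cfg_path)

  # Checksums cover the text outputs; binary plots are listed with sizes only
  # (PDF embeds a creation date, so its bytes are not reproducible).
  is_text <- grepl("\\.(tsv|json|bedgraph)$", files)
  manifest <- list(
    files = data.frame(
      path = basename(files),
      bytes = as.integer(file.size(files)),
      md5 = ifelse(is_text, unname(tools::md5sum(files)), NA_character_),
      stringsAsFactors = FALSE),
    inputs = data.frame(
      path = c(config$samples$bam, config$annotation, config$fasta),
      md5 = unname(tools::md5sum(c(config$samples$bam, config$annotation,
                                   config$fasta))),
      stringsAsFactors = FALSE),
    timings = timings,
    seed = config$seed)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(structure(list(config = config, annotation = ann, tables = tables,
                           summary = summary, manifest = manifest,
                           out_dir = config$out_dir), class = "qc_bundle"))
}
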