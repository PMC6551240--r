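flag_schema <- function() {
  tibble::tibble(sample = character(0), metric = character(0),
                 observed = numeric(0), reference = numeric(0),
                 method = character(0), flagged = logical(0),
                 detail = character(0))
}

#' Default expert QC thresholds
#'
#' Tool defaults, configurable and deliberately permissive: in-frame fraction
#' (periodicity) at least 0.50, CDS percentage at least 50, rRNA percentage
#' at most 20, tRNA percentage at most 10. Periodicity and CDS% flag when
#' low; rRNA% and tRNA% flag when high.
#'
#' @return Named list; each element a numeric vector with `min` and/or `max`.
#' @export
default_expert_thresholds <- function() {
  list(periodicity = c(min = 0.50),
       pct_CDS = c(min = 50),
       pct_rRNA = c(max = 20),
       pct_tRNA = c(max = 10))
}

#' Flag samples against expert-defined thresholds
#'
#' One flag row per sample and configured metric present in the summary;
#' metrics configured but absent from the summary are silently skipped.
#'
#' @param summary A summary tibble from [summary_table()].
#' @param thresholds Named list as in [default_expert_thresholds()].
#' @return Tibble of anomaly flags (sample, metric, observed, reference,
#'   method, flagged, detail).
#' @export
expert_threshold_flags <- function(summary,
                                   thresholds = default_expert_thresholds()) {
  rows <- list()
  for (metric in names(thresholds)) {
    if (!metric %in% colnames(summary)) next
    th <- thresholds[[metric]]
    for (i in seq_len(nrow(summary))) {
      obs <- summary[[metric]][i]
      low <- "min" %in% names(th) && !is.na(obs) && obs < th[["min"]]
      high <- "max" %in% names(th) && !is.na(obs) && obs > th[["max"]]
      ref <- if (low) th[["min"]] else if (high) th[["max"]] else
        if ("min" %in% names(th)) th[["min"]] else th[["max"]]
      detail <- if (low) {
        sprintf("%s %.4g below expert minimum %.4g", metric, obs, th[["min"]])
      } else if (high) {
        sprintf("%s %.4g above expert maximum %.4g", metric, obs, th[["max"]])
      } else {
        sprintf("%s %.4g within expert thresholds", metric, obs)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = summary$sample[i], metric = metric, observed = obs,
        reference = ref, method = "expert", flagged = low || high,
        detail = detail)
    }
  }
  if (!length(rows)) return(flag_schema())
  dplyr::bind_rows(rows)
}

#' Tukey's fences for a metric vector
#'
#' Quartiles by linear interpolation (the common type-7 convention), fence
#' multiplier `k` (1.5 by default). Values exactly on a fence are inside.
#'
#' @param x Numeric vector.
#' @param k Fence multiplier.
#' @return Numeric `c(lo, hi)`.
#' @export
tukey_fences <- function(x, k = 1.5) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  c(lo = q[1] - k * iqr, hi = q[2] + k * iqr)
}

fence_flag_rows <- function(samples, values, metric, fences, method) {
  flagged <- !is.na(values) & (values < fences[["lo"]] | values > fences[["hi"]])
  tibble::tibble(
    sample = samples, metric = metric, observed = values,
    reference = ifelse(!is.na(values) & values < fences[["lo"]],
                       fences[["lo"]], fences[["hi"]]),
    method = method, flagged = flagged,
    detail = sprintf("%s %.4g vs fence [%.4g, %.4g]", metric, values,
                     fences[["lo"]], fences[["hi"]]))
}

numeric_metrics <- function(summary) {
  cols <- colnames(summary)[vapply(summary, is.numeric, logical(1))]
  setdiff(cols, "total_alignments")
}

#' Flag outlier samples with Tukey's fence over the user's own samples
#'
#' For each metric, samples outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` computed
#' across the user samples themselves are flagged. Requires at least four
#' samples; otherwise the method is skipped with a warning.
#'
#' @param summary A summary tibble from [summary_table()].
#' @param metrics Metric columns to test; defaults to every numeric metric.
#' @param k Fence multiplier.
#' @return Tibble of anomaly flags.
#' @export
tukey_flags <- function(summary, metrics = NULL, k = 1.5) {
  if (nrow(summary) < 4L) {
    warning("Tukey's fence outlier detection needs at least 4 samples; skipped")
    return(flag_schema())
  }
  metrics <- metrics %||% numeric_metrics(summary)
  rows <- lapply(metrics, function(m) {
    v <- summary[[m]]
    if (all(is.na(v))) return(NULL)
    fence_flag_rows(summary$sample, v, m, tukey_fences(v, k), "tukey")
  })
  dplyr::bind_rows(c(list(flag_schema()), rows))
}

#' Flag samples by percent error against designated controls
#'
#' Each metric of each non-control sample is compared to the mean of the
#' control samples; the sample is flagged when the percent error
#' `|observed - control| / |control|` exceeds the threshold (default 25%).
#' Metrics whose control mean is zero are skipped with a warning.
#'
#' @param summary A summary tibble from [summary_table()].
#' @param controls Sample names designated as controls (at least one).
#' @param threshold Percent-error threshold as a fraction (default 0.25).
#' @param metrics Metric columns to test; defaults to every numeric metric.
#' @return Tibble of anomaly flags.
#' @export
control_flags <- function(summary, controls, threshold = 0.25,
                          metrics = NULL) {
  stopifnot(length(controls) >= 1L)
  missing <- setdiff(controls, summary$sample)
  if (length(missing)) {
    stop("control sample(s) not in summary: ", paste(missing, collapse = ", "))
  }
  metrics <- metrics %||% numeric_metrics(summary)
  ctl <- summary[summary$sample %in% controls, ]
  test <- summary[!summary$sample %in% controls, ]
  rows <- lapply(metrics, function(m) {
    ref <- mean(ctl[[m]], na.rm = TRUE)
    if (is.na(ref) || ref == 0) {
      warning("control mean of '", m, "' is zero or undefined; metric skipped")
      return(NULL)
    }
    pe <- abs(test[[m]] - ref) / abs(ref)
    tibble::tibble(
      sample = test$sample, metric = m, observed = test[[m]], reference = ref,
      method = "control", flagged = !is.na(pe) & pe > threshold,
      detail = sprintf("%s percent error %.4g%% vs control mean %.4g (threshold %.4g%%)",
                       m, 100 * pe, ref, 100 * threshold))
  })
  dplyr::bind_rows(c(list(flag_schema()), rows))
}

#' Flag samples against a reference metric table with Tukey's fence
#'
#' Fences are computed from the reference rows (a table of summary metrics
#' from known good-quality samples, e.g. [reference_metrics_fixture()] or a
#' user-supplied TSV) and each user sample is tested against them.
#'
#' @param summary A summary tibble from [summary_table()].
#' @param reference Reference metric table (schema-compatible with the
#'   summary) or path to its TSV.
#' @param metrics Metric columns to test; defaults to the numeric metrics
#'   shared by summary and reference.
#' @param k Fence multiplier.
#' @return Tibble of anomaly flags.
#' @export
reference_flags <- function(summary, reference, metrics = NULL, k = 1.5) {
  if (is.character(reference)) reference <- read_tsv_file(reference)
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("reference metric table is empty; supply reference QC rows")
  }
  metrics <- metrics %||%
    intersect(numeric_metrics(summary), numeric_metrics(reference))
  rows <- lapply(metrics, function(m) {
    v <- reference[[m]]
    if (all(is.na(v))) return(NULL)
    fence_flag_rows(summary$sample, summary[[m]], m, tukey_fences(v, k),
                    "reference")
  })
  dplyr::bind_rows(c(list(flag_schema()), rows))
}

#' Run all applicable anomaly-detection strategies
#'
#' @param summary A summary tibble from [summary_table()].
#' @param thresholds Expert thresholds (NULL to skip).
#' @param controls Control sample names (NULL to skip).
#' @param reference Reference metric table or TSV path (NULL to skip).
#' @param threshold Percent-error threshold for the control strategy.
#' @return Tibble of anomaly flags from every strategy run.
#' @export
detect_anomalies <- function(summary, thresholds = default_expert_thresholds(),
                             controls = NULL, reference = NULL,
                             threshold = 0.25) {
  out <- list()
  if (!is.null(thresholds)) {
    out$expert <- expert_threshold_flags(summary, thresholds)
  }
  if (nrow(summary) >= 4L) {
    out$tukey <- tukey_flags(summary)
  }
  if (!is.null(controls)) {
    out$control <- control_flags(summary, controls, threshold)
  }
  if (!is.null(reference)) {
    out$reference <- reference_flags(summary, reference)
  }
  dplyr::bind_rows(c(list(flag_schema()), out))
}
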