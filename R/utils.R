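#' @importFrom rlang .data
#' @importFrom stats quantile setNames
#' @importFrom utils head read.delim write.table
NULL

# Run code with a locally-seeded RNG, leaving the caller's RNG state alone.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_file <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
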