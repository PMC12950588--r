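#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' GENCODE/Ensembl gene identifiers carry a trailing version (`ENSG...123.7`).
#' The ChIP arm and the expression arm of an analysis are typically produced
#' by different toolchains whose annotation versions differ; the unversioned
#' identifier is the stable join key, so all readers in this package strip
#' the suffix on load.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector with any trailing `.<digits>` removed.
#' @examples
#' strip_gene_version(c("ENSG00000112096.17", "G1"))
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

# derive a reproducible sub-seed for a named stage from one master seed;
# kept below .Machine$integer.max so set.seed() always accepts it
stage_seed <- function(seed, stage) {
  offset <- c(annotation = 1L, peaks = 2L, counts = 3L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# readr wrapper: quiet, never shows column spec
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}
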