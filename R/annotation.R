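#' Default lncRNA biotype aliases
#'
#' Current GENCODE annotation uses the single biotype `lncRNA`, but older
#' releases split long non-coding genes across several legacy biotypes.
#' These aliases are folded into the lncRNA class so that analyses are
#' stable across annotation versions. `processed_transcript` is ambiguous
#' (it also covers non-lncRNA transcripts) and is only included on request.
#'
#' @param include_processed_transcript Treat `processed_transcript` as a
#'   lncRNA alias. Default `FALSE`.
#' @return Character vector of raw biotype strings mapped to `lncRNA`.
#' @export
lncrna_aliases <- function(include_processed_transcript = FALSE) {
  aliases <- c(
    "lincRNA", "antisense", "sense_intronic", "sense_overlapping",
    "3prime_overlapping_ncRNA", "bidirectional_promoter_lncRNA",
    "macro_lncRNA"
  )
  if (include_processed_transcript) aliases <- c(aliases, "processed_transcript")
  aliases
}

#' Classify raw gene biotypes into coding / lncRNA / other_noncoding
#'
#' Deterministic three-way partition used throughout the pipeline:
#' `protein_coding` maps to `coding`; `lncRNA` and the configured legacy
#' aliases map to `lncRNA`; everything else (miRNA, snoRNA, rRNA,
#' pseudogenes, TEC, unknown or missing strings) maps to `other_noncoding`.
#'
#' @param raw_biotype Character vector of annotation biotype strings.
#' @param aliases Character vector of additional biotypes treated as lncRNA;
#'   see [lncrna_aliases()].
#' @return Character vector over `c("coding", "lncRNA", "other_noncoding")`.
#' @examples
#' classify_biotype(c("protein_coding", "lncRNA", "miRNA"))
#' @export
classify_biotype <- function(raw_biotype, aliases = lncrna_aliases()) {
  out <- rep("other_noncoding", length(raw_biotype))
  out[!is.na(raw_biotype) & raw_biotype == "protein_coding"] <- "coding"
  out[!is.na(raw_biotype) & raw_biotype %in% c("lncRNA", aliases)] <- "lncRNA"
  out
}

#' Strand-aware transcription start sites
#'
#' The TSS of a gene on the plus strand is its leftmost base; on the minus
#' strand it is its rightmost base. Coordinates are 0-based half-open, so
#' the minus-strand TSS is `end - 1`.
#'
#' @param genes Data frame with columns `start`, `end` (0-based half-open)
#'   and `strand` (`"+"` or `"-"`).
#' @return Integer vector of TSS positions (0-based).
#' @export
compute_tss <- function(genes) {
  strand <- genes$strand
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "invalid strand value(s): %s (must be '+' or '-')",
      paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  as.integer(ifelse(strand == "+", genes$start, genes$end - 1L))
}

# parse one GTF attribute by key from the attribute column; NA when absent
gtf_attribute <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0('(?:^|; ?)', key, ' "([^"]*)"'))
  m[, 2]
}

#' Read gene records from a GTF annotation
#'
#' Parses GENCODE-style GTF, keeping only lines of the requested feature
#' type (by default `gene`). On-disk GTF coordinates are 1-based closed;
#' they are converted to the package-internal 0-based half-open convention
#' at this boundary, and never anywhere else. Gene identifier version
#' suffixes are stripped so that ChIP-side and expression-side tables join
#' on a stable key. Both `gene_type` (GENCODE) and `gene_biotype` (Ensembl)
#' attribute keys are recognised.
#'
#' @param gtf_path Path to a GTF file (plain text, `#` comments allowed).
#' @param feature Feature type (column 3) to keep. Default `"gene"`.
#' @param aliases lncRNA alias set passed to [classify_biotype()].
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `tss`, `raw_biotype`,
#'   `biotype_class`. Input order is preserved.
#' @export
read_gene_annotation <- function(gtf_path, feature = "gene",
                                 aliases = lncrna_aliases()) {
  if (!file.exists(gtf_path)) abort(paste0("GTF file not found: ", gtf_path))
  lines <- readr::read_lines(gtf_path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- tibble(
    gene_id = character(), gene_name = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    tss = integer(), raw_biotype = character(), biotype_class = character()
  )
  if (length(lines) == 0) return(empty)
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  lineno[i], nf[i]))
  }
  fmat <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  is_feat <- fmat[, 3] == feature
  fmat <- fmat[is_feat, , drop = FALSE]
  lineno <- lineno[is_feat]
  if (nrow(fmat) == 0) return(empty)

  start1 <- suppressWarnings(as.integer(fmat[, 4]))
  end1 <- suppressWarnings(as.integer(fmat[, 5]))
  bad <- is.na(start1) | is.na(end1) | end1 < start1
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("malformed GTF line %d: invalid coordinates '%s'-'%s'",
                  lineno[i], fmat[i, 4], fmat[i, 5]))
  }

  attrs <- fmat[, 9]
  gene_id <- gtf_attribute(attrs, "gene_id")
  if (anyNA(gene_id)) {
    abort(sprintf("malformed GTF line %d: missing gene_id attribute",
                  lineno[which(is.na(gene_id))[1]]))
  }
  gene_id <- strip_gene_version(gene_id)
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    abort(sprintf("duplicate gene_id after version-stripping: %s", dup))
  }
  gene_name <- gtf_attribute(attrs, "gene_name")
  gene_name[is.na(gene_name)] <- ""
  raw_biotype <- dplyr::coalesce(
    gtf_attribute(attrs, "gene_type"),
    gtf_attribute(attrs, "gene_biotype")
  )
  if (anyNA(raw_biotype)) {
    warn(sprintf(
      "%d gene(s) without gene_type/gene_biotype attribute; classified as other_noncoding",
      sum(is.na(raw_biotype))
    ))
  }

  genes <- tibble(
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = fmat[, 1],
    start = start1 - 1L,
    end = end1,
    strand = fmat[, 7],
    raw_biotype = ifelse(is.na(raw_biotype), "", raw_biotype),
    biotype_class = classify_biotype(raw_biotype, aliases)
  )
  genes$tss <- compute_tss(genes)
  genes[, c("gene_id", "gene_name", "chrom", "start", "end", "strand",
            "tss", "raw_biotype", "biotype_class")]
}

#' Write gene records back to GTF
#'
#' Inverse of [read_gene_annotation()]: internal 0-based half-open
#' coordinates become 1-based closed on disk. Round-tripping a loaded
#' annotation through write and read yields identical records.
#'
#' @param genes Tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- sprintf(
    '%s\tlncregulon\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_type "%s";',
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_name, genes$raw_biotype
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Promoter windows around transcription start sites
#'
#' One window per gene, centred on its strand-aware TSS. A position `p`
#' belongs to the window iff `|p - tss| <= radius`; membership is defined
#' by distance (inclusive at both boundaries), so clipping at chromosome
#' start never changes semantics. Windows of different genes may overlap.
#'
#' @param genes Tibble from [read_gene_annotation()].
#' @param radius Window half-width in nucleotides (default 2000).
#' @return Tibble: `gene_id`, `chrom`, `tss`, `strand`, `radius`.
#' @export
promoter_windows <- function(genes, radius = 2000) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("radius must be a single positive number")
  }
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    tss = genes$tss,
    strand = genes$strand,
    radius = as.integer(radius)
  )
}
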