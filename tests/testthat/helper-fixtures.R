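# shared in-code fixtures

# write a small GENCODE-style GTF and return its path
write_test_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_gene_line <- function(chrom = "chr1", start1 = 1001, end1 = 5000,
                          strand = "+", gene_id = "G1",
                          gene_name = "GENE1", gene_type = "protein_coding",
                          feature = "gene") {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_type "%s";',
          chrom, feature, start1, end1, strand, gene_id, gene_name, gene_type)
}

# narrowPeak line builder (0-based half-open on disk)
np_line <- function(chrom = "chr1", start = 100, end = 400, name = "p",
                    score5 = 0, signal = 600, summit = -1) {
  sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
          chrom, start, end, name, score5, format(signal), summit)
}

# brute-force reference for promoter assignment: explicit peak x gene scan
brute_force_assign <- function(peaks, windows) {
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(peaks))) {
    same <- windows$chrom == peaks$chrom[i]
    d <- peaks$anchor[i] - windows$tss
    hit <- which(same & abs(d) <= windows$radius)
    for (j in hit) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        peak = i, gene_id = windows$gene_id[j],
        distance_to_tss = if (windows$strand[j] == "-") -d[j] else d[j]
      )
    }
  }
  if (k == 0L) {
    return(data.frame(peak = integer(), gene_id = character(),
                      distance_to_tss = integer()))
  }
  do.call(rbind, rows)
}

# random peak/window instance on a small genome
random_instance <- function(n_peaks, n_genes, radius = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- c("c1", "c2", "c3")
  peaks <- tibble::tibble(
    chrom = sample(chroms, n_peaks, replace = TRUE),
    start = sample.int(50000, n_peaks),
    name = paste0("p", seq_len(n_peaks)),
    height = stats::runif(n_peaks, 1, 100),
    width = sample(100:500, n_peaks, replace = TRUE)
  )
  peaks$end <- peaks$start + peaks$width
  peaks$score <- peaks$height / peaks$width
  peaks$anchor <- as.integer(peaks$start + peaks$width %/% 2)
  windows <- tibble::tibble(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    tss = sample.int(50000, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    radius = as.integer(radius)
  )
  list(peaks = peaks, windows = windows)
}

# the twelve published knockdown log2 fold changes used as a worked example:
# four gained expression, eight lost expression upon TF knockdown
published_shortlist_lfc <- function() {
  tibble::tibble(
    gene_name = c("GLUD1P2", "FAB5P3", "JPX", "SMPD4BP",
                  "ZFAS1", "LINC00862", "SNHG32", "LINC01962",
                  "SNHG12", "1QCH-AS1", "LINC00324", "DCXR-DT"),
    log2fc = c(1.430810162, 1.294400533, 1.190768343, 1.085042792,
               -1.002422386, -1.1273027, -1.209326334, -1.236866821,
               -1.305098141, -1.70573314, -1.823152463, -2.310831734)
  )
}
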