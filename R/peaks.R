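#' Read ChIP-seq peaks from narrowPeak or BED
#'
#' Each peak carries a signal magnitude ("height"), a width (`end - start`),
#' and the ranking score `height / width` used for background filtering.
#' For the ENCODE narrowPeak dialect (BED6+4) the height is taken from the
#' signalValue column (column 7) by default — the measurement-scale
#' quantity — or from the integer display score (column 5) via
#' `height_column = "score"`. The anchor, the single position measured
#' against the TSS, is the summit (`start` + column 10) when a summit
#' offset is recorded, otherwise the interval midpoint. Plain BED uses
#' column 5 as height and the midpoint as anchor.
#'
#' BED-family coordinates are already 0-based half-open and are kept as-is.
#'
#' @param path Peak file path.
#' @param dialect `"narrowPeak"` (default) or `"bed"`.
#' @param height_column For narrowPeak: `"signalValue"` (column 7, default)
#'   or `"score"` (column 5).
#' @return Tibble: `chrom`, `start`, `end`, `name`, `height`, `width`,
#'   `score`, `anchor`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed"),
                       height_column = c("signalValue", "score")) {
  dialect <- match.arg(dialect)
  height_column <- match.arg(height_column)
  if (!file.exists(path)) abort(paste0("peak file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), height = double(), width = integer(),
    score = double(), anchor = integer()
  )
  if (length(lines) == 0) return(empty)
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed peak line %d: fewer than 3 columns",
                  lineno[which(nf < 3)[1]]))
  }
  col <- function(j) vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_, "")
  chrom <- col(1)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- is.na(start) | is.na(end) | end <= start
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("malformed peak line %d: end must exceed start ('%s'-'%s')",
                  lineno[i], col(2)[i], col(3)[i]))
  }
  name <- col(4)
  name[is.na(name) | name == "."] <- ""
  midpoint <- as.integer((start + end) %/% 2L)

  if (dialect == "narrowPeak") {
    if (any(nf < 10)) {
      abort(sprintf("malformed narrowPeak line %d: expected 10 columns, found %d",
                    lineno[which(nf < 10)[1]], nf[which(nf < 10)[1]]))
    }
    height <- suppressWarnings(as.numeric(col(if (height_column == "signalValue") 7L else 5L)))
    summit <- suppressWarnings(as.integer(col(10)))
    anchor <- ifelse(!is.na(summit) & summit >= 0L, start + summit, midpoint)
  } else {
    if (any(nf < 5)) {
      abort(paste0(
        "BED line ", lineno[which(nf < 5)[1]], " has no score column to use as ",
        "peak height; supply narrowPeak or 5-column BED"
      ))
    }
    height <- suppressWarnings(as.numeric(col(5)))
    anchor <- midpoint
  }
  if (anyNA(height)) {
    abort(sprintf("malformed peak line %d: non-numeric height",
                  lineno[which(is.na(height))[1]]))
  }
  width <- end - start
  tibble(
    chrom = chrom, start = start, end = end, name = name,
    height = height, width = width, score = height / width,
    anchor = as.integer(anchor)
  )
}

#' First-quartile threshold of peak scores
#'
#' The 25th percentile (or any quantile `q`) computed by linear
#' interpolation between closest order statistics — the convention where
#' quantile `q` of the sorted values interpolates at position
#' `1 + (n - 1) q`. Fixed and documented because quartile definitions
#' differ across tools.
#'
#' @param scores Non-empty numeric vector of non-negative scores.
#' @param q Quantile in (0, 1); default 0.25.
#' @return The threshold as a single number.
#' @examples
#' quartile_threshold(c(1, 2, 3, 4)) # 1.75
#' @export
quartile_threshold <- function(scores, q = 0.25) {
  if (length(scores) == 0) abort("cannot compute a quantile of an empty score set")
  if (anyNA(scores)) abort("scores must not contain missing values")
  unname(quantile(scores, probs = q, type = 7))
}

#' Discard background peaks below the first quartile of the ranking score
#'
#' Peaks whose `height / width` score falls strictly below the first
#' quartile of all input scores are treated as background noise and
#' removed; ties at the threshold are retained ("falling below" read
#' literally). Input order is preserved.
#'
#' @param peaks Tibble from [read_peaks()].
#' @param q Quantile used as the cutoff (default 0.25).
#' @return The kept peaks, with attributes `threshold` (the cutoff, `NA`
#'   for empty input), `removed` (tibble of discarded peaks) and
#'   `n_input`.
#' @export
filter_background <- function(peaks, q = 0.25) {
  if (nrow(peaks) == 0) {
    out <- peaks
    attr(out, "threshold") <- NA_real_
    attr(out, "removed") <- peaks
    attr(out, "n_input") <- 0L
    return(out)
  }
  thr <- quartile_threshold(peaks$score, q)
  keep <- peaks$score >= thr
  out <- peaks[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "removed") <- peaks[!keep, , drop = FALSE]
  attr(out, "n_input") <- nrow(peaks)
  out
}

#' Assign peaks to promoter windows
#'
#' Emits one assignment for every (peak, window) pair on the same
#' chromosome whose anchor lies within `radius` of the TSS
#' (`|anchor - tss| <= radius`, boundaries inclusive). A peak may hit
#' several genes and a gene may collect several peaks. The signed distance
#' is oriented by the gene: negative values are upstream of the gene on
#' its own strand. Overlap is computed with IRanges interval indexing and
#' is exactly equivalent to the brute-force double loop over all pairs.
#'
#' @param peaks Tibble from [read_peaks()] (or [filter_background()]).
#' @param windows Tibble from [promoter_windows()].
#' @return Tibble: peak columns prefixed `peak_` (`peak_chrom`,
#'   `peak_start`, `peak_end`, `peak_name`, `peak_height`, `peak_width`,
#'   `peak_score`), `anchor`, `gene_id`, `distance_to_tss`.
#' @export
assign_to_promoters <- function(peaks, windows) {
  empty <- tibble(
    peak_chrom = character(), peak_start = integer(), peak_end = integer(),
    peak_name = character(), peak_height = double(), peak_width = integer(),
    peak_score = double(), anchor = integer(), gene_id = character(),
    distance_to_tss = integer()
  )
  if (nrow(peaks) == 0 || nrow(windows) == 0) return(empty)
  shared <- intersect(unique(peaks$chrom), unique(windows$chrom))
  if (length(shared) == 0) {
    inform("no chromosome names shared between peaks and promoter windows; no assignments")
    return(empty)
  }
  # shift everything right so window starts stay positive near chromosome 0;
  # a constant shift cannot change |anchor - tss|
  shift <- max(windows$radius) + 1L
  p_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$anchor + shift, width = 1L)
  )
  w_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$tss - windows$radius + shift,
                     end = windows$tss + windows$radius + shift)
  )
  hits <- GenomicRanges::findOverlaps(p_gr, w_gr)
  pi <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  raw_d <- peaks$anchor[pi] - windows$tss[wi]
  signed <- ifelse(windows$strand[wi] == "-", -raw_d, raw_d)
  out <- tibble(
    peak_chrom = peaks$chrom[pi],
    peak_start = peaks$start[pi],
    peak_end = peaks$end[pi],
    peak_name = peaks$name[pi],
    peak_height = peaks$height[pi],
    peak_width = peaks$width[pi],
    peak_score = peaks$score[pi],
    anchor = peaks$anchor[pi],
    gene_id = windows$gene_id[wi],
    distance_to_tss = as.integer(signed)
  )
  arrange(out, match(.data$gene_id, windows$gene_id), .data$peak_start)
}

#' Bound genes and their best peaks, partitioned by biotype
#'
#' Deduplicates promoter assignments to the set of bound genes and attaches
#' each gene's best supporting peak: maximum score, ties broken by smallest
#' `|distance_to_tss|`, then leftmost start. Biotype partition counts are
#' attached as an attribute.
#'
#' @param assignments Tibble from [assign_to_promoters()].
#' @param genes Tibble from [read_gene_annotation()]; every assigned
#'   `gene_id` must be present.
#' @return Tibble with one row per bound gene: `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `biotype_class`, `n_peaks`, `best_peak_score`,
#'   `best_peak_start`, `best_peak_end`, `best_peak_height`,
#'   `best_peak_width`, `distance_to_tss`; attribute `partition` holds the
#'   named count vector over the three biotype classes.
#' @export
genes_with_binding <- function(assignments, genes) {
  unknown <- setdiff(assignments$gene_id, genes$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("assignments refer to unknown gene_id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  bound <- assignments |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$peak_score), abs(.data$distance_to_tss),
            .data$peak_start, .by_group = TRUE) |>
    summarise(
      n_peaks = n(),
      best_peak_score = first(.data$peak_score),
      best_peak_start = first(.data$peak_start),
      best_peak_end = first(.data$peak_end),
      best_peak_height = first(.data$peak_height),
      best_peak_width = first(.data$peak_width),
      distance_to_tss = first(.data$distance_to_tss),
      .groups = "drop"
    ) |>
    inner_join(
      genes[, c("gene_id", "gene_name", "chrom", "strand", "biotype_class")],
      by = "gene_id"
    ) |>
    select("gene_id", "gene_name", "chrom", "strand", "biotype_class",
           "n_peaks", "best_peak_score", "best_peak_start", "best_peak_end",
           "best_peak_height", "best_peak_width", "distance_to_tss") |>
    arrange(match(.data$gene_id, genes$gene_id))
  partition <- c(
    coding = sum(bound$biotype_class == "coding"),
    lncRNA = sum(bound$biotype_class == "lncRNA"),
    other_noncoding = sum(bound$biotype_class == "other_noncoding")
  )
  attr(bound, "partition") <- partition
  bound
}

#' Histogram of peak ranking scores with the background cutoff
#'
#' @param peaks Tibble from [read_peaks()].
#' @param q Quantile drawn as the cutoff line (default 0.25).
#' @return A ggplot object.
#' @export
plot_peak_scores <- function(peaks, q = 0.25) {
  thr <- if (nrow(peaks) > 0) quartile_threshold(peaks$score, q) else NA_real_
  p <- ggplot2::ggplot(peaks, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey60") +
    ggplot2::labs(x = "peak score (height / width)", y = "peaks") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, colour = "#b2182b",
                                 linetype = "dashed")
  }
  p
}
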