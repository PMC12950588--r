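#' Read a gene-level count matrix with a condition map
#'
#' Counts are a TSV whose first column holds gene identifiers and whose
#' remaining, header-named columns hold one sample each. The condition map
#' links each sample to `control` or `knockdown`, either as a two-column
#' TSV (`sample_id`, `condition`) or as a named character vector.
#'
#' @param path Counts TSV path.
#' @param conditions Path to a condition-map TSV, or a named character
#'   vector `c(sample = "control", ...)`.
#' @return An object of class `count_matrix`: a list with `counts`
#'   (integer matrix, genes x samples, version-stripped rownames) and
#'   `samples` (tibble: `sample_id`, `condition`).
#' @export
read_counts <- function(path, conditions) {
  tbl <- read_tsv_quiet(path)
  if (ncol(tbl) < 2) abort("counts file must have gene ids plus at least one sample column")
  gene_ids <- strip_gene_version(as.character(tbl[[1]]))
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicate gene id in counts: %s",
                  gene_ids[duplicated(gene_ids)][1]))
  }
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort("counts must be numeric")
  if (any(is.na(mat))) abort("counts must not contain missing values")
  if (any(mat < 0)) abort("counts must be non-negative")
  if (any(mat != floor(mat))) {
    abort(sprintf("counts must be integers (found %s)", mat[mat != floor(mat)][1]))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- gene_ids

  if (is.character(conditions) && length(conditions) == 1 && file.exists(conditions)) {
    cmap <- read_tsv_quiet(conditions)
    if (ncol(cmap) < 2) abort("condition map must have two columns: sample_id, condition")
    conditions <- stats::setNames(as.character(cmap[[2]]), as.character(cmap[[1]]))
  }
  if (is.null(names(conditions)) || anyNA(names(conditions))) {
    abort("conditions must be named by sample id")
  }
  missing <- setdiff(colnames(mat), names(conditions))
  if (length(missing) > 0) {
    abort(sprintf("no condition given for sample(s): %s", paste(missing, collapse = ", ")))
  }
  cond <- unname(conditions[colnames(mat)])
  bad <- !cond %in% c("control", "knockdown")
  if (any(bad)) {
    abort(sprintf("condition labels must be 'control' or 'knockdown' (found '%s')",
                  cond[bad][1]))
  }
  structure(
    list(
      counts = mat,
      samples = tibble(sample_id = colnames(mat), condition = cond)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d control, %d knockdown)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "knockdown")))
  invisible(x)
}

as_count_input <- function(counts) {
  if (inherits(counts, "count_matrix")) return(counts$counts)
  if (is.matrix(counts)) return(counts)
  abort("expected a count_matrix or a numeric matrix")
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene with all-positive
#' counts the geometric mean across samples is computed; a sample's factor
#' is the median over those genes of `count / geometric mean`, and the
#' factors are rescaled to have geometric mean 1. A total-count fallback
#' (`method = "total"`, factors proportional to column sums) is available
#' for matrices with no all-positive gene.
#'
#' @param counts A `count_matrix` or numeric matrix (genes x samples).
#' @param method `"median-ratio"` (default) or `"total"`.
#' @return Named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @export
size_factors <- function(counts, method = c("median-ratio", "total")) {
  method <- match.arg(method)
  mat <- as_count_input(counts)
  if (ncol(mat) == 1) return(stats::setNames(1, colnames(mat)))
  if (method == "total") {
    sf <- colSums(mat)
    if (any(sf <= 0)) abort("total-count size factors need positive column sums")
  } else {
    all_pos <- rowSums(mat <= 0) == 0
    if (!any(all_pos)) {
      abort(paste0(
        "no gene has positive counts in every sample; ",
        "median-of-ratios is undefined — use method = \"total\""
      ))
    }
    lg <- rowMeans(log(mat[all_pos, , drop = FALSE]))
    sf <- apply(mat[all_pos, , drop = FALSE], 2, function(s) median(exp(log(s) - lg)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(mat))
}

#' Two-group negative-binomial Wald test
#'
#' A deliberately simple, fully documented differential-expression stage
#' for a control vs knockdown design: counts are depth-normalised by
#' median-of-ratios size factors; the log2 fold change is
#' `log2((mu_k + pseudocount) / (mu_c + pseudocount))` over the normalised
#' condition means (knockdown relative to control); a per-gene dispersion
#' is estimated by method of moments from the pooled within-group variance
#' of normalised counts, stabilised by a moment average toward the
#' genome-wide mean dispersion (`prior_df` pseudo-observations against the
#' `n1 + n2 - 2` residual degrees of freedom per gene) and floored at
#' `1e-8`; the Wald statistic divides the log2 fold change by its
#' delta-method standard error under the NB variance
#' `mu + dispersion * mu^2`, with a two-sided p-value from the standard
#' normal. The moment average is what keeps the normal reference honest on
#' few-replicate designs: a raw per-gene variance with ~4 degrees of
#' freedom plugged into a normal-reference Wald statistic roughly doubles
#' the nominal type-I error. No empirical-Bayes machinery, fold-change
#' shrinkage or independent filtering is performed; externally produced DE
#' tables can be substituted via [read_de_table()].
#'
#' Genes with zero counts in every sample get `NA` p-values.
#'
#' @param counts A `count_matrix` from [read_counts()], or a numeric
#'   matrix together with `conditions`.
#' @param conditions Character vector over `{control, knockdown}`, one per
#'   column; taken from the `count_matrix` when omitted.
#' @param pseudocount Added to both normalised means in the fold change
#'   only (default 0.5), stabilising low/zero-count genes.
#' @param dispersion_floor Lower bound for the moment dispersion estimate.
#' @param prior_df Weight (in pseudo degrees of freedom) of the
#'   genome-wide mean dispersion in the per-gene moment average
#'   (default 20); `0` gives the raw per-gene estimator.
#' @param sf_method Size-factor method, see [size_factors()].
#' @return Tibble: `gene_id`, `base_mean`, `log2fc`, `pvalue` (`padj`,
#'   `significant`, `direction` are added by [bh_adjust()] /
#'   [apply_de_filters()]).
#' @export
nb_wald_test <- function(counts, conditions = NULL, pseudocount = 0.5,
                         dispersion_floor = 1e-8, prior_df = 20,
                         sf_method = c("median-ratio", "total")) {
  sf_method <- match.arg(sf_method)
  if (inherits(counts, "count_matrix")) {
    conditions <- conditions %||% counts$samples$condition
    counts <- counts$counts
  }
  if (is.null(conditions)) abort("conditions are required with a bare matrix")
  if (length(conditions) != ncol(counts)) {
    abort("conditions must have one label per sample column")
  }
  n_c <- sum(conditions == "control")
  n_k <- sum(conditions == "knockdown")
  if (n_c < 2 || n_k < 2) {
    abort(sprintf(
      "need at least 2 samples per condition for testing (control: %d, knockdown: %d)",
      n_c, n_k
    ))
  }
  sf <- size_factors(counts, method = sf_method)
  norm <- sweep(counts, 2, sf, "/")
  nc_mat <- norm[, conditions == "control", drop = FALSE]
  nk_mat <- norm[, conditions == "knockdown", drop = FALSE]
  mu_c <- rowMeans(nc_mat)
  mu_k <- rowMeans(nk_mat)
  v_c <- apply(nc_mat, 1, var)
  v_k <- apply(nk_mat, 1, var)
  df <- n_c + n_k - 2
  pooled_var <- ((n_c - 1) * v_c + (n_k - 1) * v_k) / df
  mu_bar <- (n_c * mu_c + n_k * mu_k) / (n_c + n_k)
  raw_disp <- ifelse(mu_bar > 0, (pooled_var - mu_bar) / mu_bar^2, 0)
  mean_disp <- if (any(mu_bar > 0)) mean(raw_disp[mu_bar > 0]) else 0
  dispersion <- pmax((df * raw_disp + prior_df * mean_disp) / (df + prior_df),
                     dispersion_floor)
  log2fc <- log2((mu_k + pseudocount) / (mu_c + pseudocount))
  var_mu_c <- (mu_c + dispersion * mu_c^2) / n_c
  var_mu_k <- (mu_k + dispersion * mu_k^2) / n_k
  se <- sqrt(var_mu_c / (mu_c + pseudocount)^2 +
               var_mu_k / (mu_k + pseudocount)^2) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  all_zero <- rowSums(counts) == 0
  pvalue[all_zero | !is.finite(stat)] <- NA_real_
  tibble(
    gene_id = rownames(counts) %||% paste0("gene", seq_len(nrow(counts))),
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(log2fc),
    pvalue = unname(pvalue)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take running minima of
#' `p * m / rank` from the largest rank down, cap at 1, return in input
#' order. Missing values pass through untouched and do not count towards
#' `m`.
#'
#' @param pvalues Numeric vector in \[0, 1\], `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Apply significance and direction filters to DE results
#'
#' A gene is significant iff its adjusted p-value is strictly below
#' `alpha` and its absolute log2 fold change is at least `lfc_threshold`
#' (missing `padj` means not significant). Direction is `up` / `down` by
#' the sign of the fold change for significant genes, `none` otherwise.
#'
#' @param results Tibble with `log2fc` and `padj` columns (e.g.
#'   [nb_wald_test()] output after [bh_adjust()], or [read_de_table()]).
#' @param lfc_threshold Minimum |log2FC|, inclusive (default 0.5).
#' @param alpha Adjusted-p cutoff, strict (default 0.05).
#' @return `results` with `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"none"`) columns filled.
#' @export
apply_de_filters <- function(results, lfc_threshold = 0.5, alpha = 0.05) {
  if (lfc_threshold < 0) abort("lfc_threshold must be >= 0")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  results |>
    mutate(
      significant = !is.na(.data$padj) & .data$padj < alpha &
        abs(.data$log2fc) >= lfc_threshold,
      direction = dplyr::case_when(
        .data$significant & .data$log2fc > 0 ~ "up",
        .data$significant & .data$log2fc < 0 ~ "down",
        .default = "none"
      )
    )
}

#' Read a precomputed differential-expression table
#'
#' Accepts the output of any external DE tool as a TSV with header-named
#' columns `gene_id`, `log2fc`, `pvalue`, `padj` (any order; extra columns
#' such as `gene_name` or `base_mean` are carried along when present,
#' otherwise ignored). `NA` or empty cells become missing values.
#' Significance filters are NOT applied here; see [apply_de_filters()].
#'
#' @param path DE table TSV path.
#' @return Tibble: `gene_id` (version-stripped), `gene_name` (if present),
#'   `base_mean` (if present, else `NA`), `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  tbl <- read_tsv_quiet(path, na = c("", "NA"))
  required <- c("gene_id", "log2fc", "pvalue", "padj")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("DE table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(
    gene_id = strip_gene_version(as.character(tbl$gene_id)),
    log2fc = as.numeric(tbl$log2fc),
    pvalue = as.numeric(tbl$pvalue),
    padj = as.numeric(tbl$padj)
  )
  if ("gene_name" %in% names(tbl)) out$gene_name <- as.character(tbl$gene_name)
  if ("base_mean" %in% names(tbl)) out$base_mean <- as.numeric(tbl$base_mean)
  out
}

#' Volcano-style plot of DE results
#'
#' @param results Filtered DE tibble from [apply_de_filters()].
#' @param lfc_threshold,alpha Thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, lfc_threshold = 0.5, alpha = 0.05) {
  dat <- dplyr::filter(results, !is.na(.data$padj))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$padj), colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", none = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change (knockdown / control)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}
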