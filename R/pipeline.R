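#' Binding-evidence stage: peaks -> filtered -> promoter assignments -> bound genes
#'
#' Runs [read_peaks()], [filter_background()] (optional),
#' [assign_to_promoters()] and [genes_with_binding()] and writes two TSVs
#' into `out_dir`: `assignments.tsv` (one row per kept peak x promoter
#' hit, with gene name and biotype attached) and `bound_genes.tsv` (one
#' row per bound gene with best-peak columns). The funnel of counts after
#' each step is logged to stderr.
#'
#' @param peaks_path,gtf_path Input files.
#' @param out_dir Output directory (created if needed).
#' @param dialect,height_column Passed to [read_peaks()].
#' @param radius Promoter half-width (default 2000 nt).
#' @param quartile Background quantile cutoff (default 0.25).
#' @param quartile_filter Set `FALSE` to skip background filtering, or to
#'   apply it after promoter assignment via `filter_after_assignment`.
#' @param filter_after_assignment Apply the quartile filter to
#'   promoter-assigned peaks instead of genome-wide (sensitivity
#'   analysis; default `FALSE`, i.e. ranking precedes shortlisting).
#' @param aliases lncRNA alias set, see [lncrna_aliases()].
#' @return Invisibly, a list: `assignments`, `bound`, `threshold`, `paths`.
#' @export
run_annotate <- function(peaks_path, gtf_path, out_dir,
                         dialect = "narrowPeak",
                         height_column = "signalValue",
                         radius = 2000, quartile = 0.25,
                         quartile_filter = TRUE,
                         filter_after_assignment = FALSE,
                         aliases = lncrna_aliases()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_gene_annotation(gtf_path, aliases = aliases)
  peaks <- read_peaks(peaks_path, dialect = dialect,
                      height_column = height_column)
  inform(sprintf("annotate: %d peaks read, %d genes read", nrow(peaks), nrow(genes)))

  threshold <- NA_real_
  if (quartile_filter && !filter_after_assignment) {
    peaks <- filter_background(peaks, q = quartile)
    threshold <- attr(peaks, "threshold")
    inform(sprintf("annotate: %d peaks kept above score threshold %s",
                   nrow(peaks), format(threshold)))
  }
  windows <- promoter_windows(genes, radius = radius)
  assignments <- assign_to_promoters(peaks, windows)
  if (quartile_filter && filter_after_assignment && nrow(assignments) > 0) {
    threshold <- quartile_threshold(assignments$peak_score, q = quartile)
    assignments <- assignments[assignments$peak_score >= threshold, , drop = FALSE]
    inform(sprintf("annotate: %d assignments kept above score threshold %s",
                   nrow(assignments), format(threshold)))
  }
  inform(sprintf("annotate: %d peak-promoter assignments", nrow(assignments)))
  bound <- genes_with_binding(assignments, genes)
  part <- attr(bound, "partition")
  inform(sprintf("annotate: %d bound genes (coding %d / lncRNA %d / other %d)",
                 nrow(bound), part[["coding"]], part[["lncRNA"]],
                 part[["other_noncoding"]]))

  assignments_out <- assignments |>
    left_join(genes[, c("gene_id", "gene_name", "biotype_class")], by = "gene_id") |>
    select("peak_chrom", "peak_start", "peak_end", "peak_name", "peak_height",
           "peak_width", "peak_score", "anchor", "gene_id", "gene_name",
           "biotype_class", "distance_to_tss")
  paths <- list(assignments = file.path(out_dir, "assignments.tsv"),
                bound = file.path(out_dir, "bound_genes.tsv"))
  readr::write_tsv(assignments_out, paths$assignments, progress = FALSE)
  readr::write_tsv(bound, paths$bound, progress = FALSE)
  invisible(list(assignments = assignments_out, bound = bound,
                 threshold = threshold, paths = paths))
}

#' Differential-expression stage
#'
#' Either runs the built-in NB Wald stand-in on a count matrix
#' (`counts_path` + `conditions_path`) or re-filters an externally
#' produced DE table (`de_table_path`) — exactly one input route must be
#' given. Writes `de_results.tsv` with columns `gene_id`, `base_mean`,
#' `log2fc`, `pvalue`, `padj`, `significant`, `direction` (plus
#' `gene_name` when the external table provides it).
#'
#' @param out_dir Output directory.
#' @param counts_path,conditions_path Count-matrix route inputs.
#' @param de_table_path External DE-table route input.
#' @param lfc_threshold,alpha Significance filters, see
#'   [apply_de_filters()].
#' @return Invisibly, a list: `de` (the filtered tibble), `paths`.
#' @export
run_de <- function(out_dir, counts_path = NULL, conditions_path = NULL,
                   de_table_path = NULL, lfc_threshold = 0.5, alpha = 0.05) {
  have_counts <- !is.null(counts_path)
  have_table <- !is.null(de_table_path)
  if (have_counts == have_table) {
    abort("supply exactly one of counts_path (+ conditions_path) or de_table_path")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (have_counts) {
    if (is.null(conditions_path)) abort("conditions_path is required with counts_path")
    cm <- read_counts(counts_path, conditions_path)
    de <- nb_wald_test(cm)
    de$padj <- bh_adjust(de$pvalue)
  } else {
    de <- read_de_table(de_table_path)
  }
  de <- apply_de_filters(de, lfc_threshold = lfc_threshold, alpha = alpha)
  inform(sprintf("de: %d genes tested, %d significant (up %d / down %d)",
                 nrow(de), sum(de$significant),
                 sum(de$direction == "up"), sum(de$direction == "down")))
  front <- intersect(c("gene_id", "gene_name", "base_mean", "log2fc",
                       "pvalue", "padj", "significant", "direction"),
                     names(de))
  de <- de[, front]
  paths <- list(de = file.path(out_dir, "de_results.tsv"))
  readr::write_tsv(de, paths$de, progress = FALSE)
  invisible(list(de = de, paths = paths))
}

#' Integration stage: intersect binding and DE evidence
#'
#' Reads the `bound_genes.tsv` and `de_results.tsv` flat files written by
#' [run_annotate()] and [run_de()] (so either arm can be replaced by an
#' external run), intersects them with [intersect_targets()], and writes
#' `shortlist.tsv` plus `report.json`.
#'
#' @param bound_path,de_path Stage handoff TSVs.
#' @param out_dir Output directory.
#' @param gtf_path Optional annotation; when given, DE direction counts in
#'   the report are restricted to lncRNA genes.
#' @param biotype Binding-arm biotype restriction (default `"lncRNA"`).
#' @param lfc_threshold,alpha Filters re-applied to the DE table before
#'   intersection, so a stricter shortlist can be cut from a laxer DE run.
#' @param name_fallback Enable gene-name fallback join.
#' @return Invisibly, a list: `shortlist`, `report`, `paths`.
#' @export
run_intersect <- function(bound_path, de_path, out_dir, gtf_path = NULL,
                          biotype = "lncRNA", lfc_threshold = 0.5,
                          alpha = 0.05, name_fallback = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bound <- read_tsv_quiet(bound_path)
  de <- read_tsv_quiet(de_path)
  de <- apply_de_filters(de, lfc_threshold = lfc_threshold, alpha = alpha)
  genes <- if (!is.null(gtf_path)) read_gene_annotation(gtf_path) else NULL
  shortlist <- intersect_targets(bound, de, biotype = biotype,
                                 name_fallback = name_fallback)
  report <- summarize_integration(
    bound, de, shortlist, genes = genes,
    parameters = list(biotype = biotype, lfc_threshold = lfc_threshold,
                      alpha = alpha, name_fallback = name_fallback)
  )
  inform(sprintf("intersect: %d shortlist entries (up %d / down %d)",
                 report$counts$n_shortlist, report$counts$n_shortlist_up,
                 report$counts$n_shortlist_down))
  paths <- list(shortlist = file.path(out_dir, "shortlist.tsv"),
                report = file.path(out_dir, "report.json"))
  readr::write_tsv(shortlist, paths$shortlist, progress = FALSE)
  write_report_json(report, paths$report)
  invisible(list(shortlist = shortlist, report = report, paths = paths))
}

#' Generate a synthetic fixture directory
#'
#' Thin wrapper over [simulate_dataset()] accepting either a
#' [simulation_config()] or a flat key-value config file.
#'
#' @param config A `sim_config`, or a path to a flat config file
#'   (see [read_pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) {
    cfg <- read_pipeline_config(config)
    keep <- intersect(names(cfg), names(formals(simulation_config)))
    config <- do.call(simulation_config, cfg[keep])
  }
  simulate_dataset(config, out_dir)
}

#' Run the full pipeline: annotate, DE, intersect
#'
#' Composes the three stages with one configuration; the result is
#' byte-identical to running [run_annotate()], [run_de()] and
#' [run_intersect()] individually into the same directory.
#'
#' @param peaks_path,gtf_path Binding-arm inputs.
#' @param out_dir Output directory.
#' @param counts_path,conditions_path,de_table_path DE-arm inputs (exactly
#'   one route), see [run_de()].
#' @param dialect,height_column,radius,quartile,quartile_filter Binding-arm
#'   options, see [run_annotate()].
#' @param lfc_threshold,alpha,biotype,name_fallback DE/integration options.
#' @return Invisibly, a list with each stage's result and all output paths.
#' @export
run_all <- function(peaks_path, gtf_path, out_dir,
                    counts_path = NULL, conditions_path = NULL,
                    de_table_path = NULL,
                    dialect = "narrowPeak", height_column = "signalValue",
                    radius = 2000, quartile = 0.25, quartile_filter = TRUE,
                    lfc_threshold = 0.5, alpha = 0.05,
                    biotype = "lncRNA", name_fallback = TRUE) {
  for (p in c(peaks_path, gtf_path, counts_path, conditions_path, de_table_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("input file not found: ", p))
  }
  ann <- run_annotate(peaks_path, gtf_path, out_dir, dialect = dialect,
                      height_column = height_column, radius = radius,
                      quartile = quartile, quartile_filter = quartile_filter)
  de <- run_de(out_dir, counts_path = counts_path,
               conditions_path = conditions_path,
               de_table_path = de_table_path,
               lfc_threshold = lfc_threshold, alpha = alpha)
  int <- run_intersect(ann$paths$bound, de$paths$de, out_dir,
                       gtf_path = gtf_path, biotype = biotype,
                       lfc_threshold = lfc_threshold, alpha = alpha,
                       name_fallback = name_fallback)
  invisible(list(annotate = ann, de = de, intersect = int,
                 paths = c(ann$paths, de$paths, int$paths)))
}

#' Read a flat key-value pipeline configuration file
#'
#' One `key value` (or `key = value`) pair per line; `#` comments and
#' blank lines ignored. Values that parse as numbers become numeric;
#' comma-separated values become vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- stringr::str_match(ln, "^([A-Za-z_][A-Za-z0-9_]*)\\s*(?:=|\\s)\\s*(.*)$")
    if (is.na(m[1, 1])) abort(paste0("cannot parse config line: ", ln))
    key <- m[1, 2]
    val <- trimws(m[1, 3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
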