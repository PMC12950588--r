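#' Infer the candidate regulation mode from the knockdown response
#'
#' Under a knockdown design the modelling convention is: expression LOSS
#' upon TF knockdown marks the gene as a candidate the TF activates;
#' expression GAIN marks a candidate the TF represses. Indirect effects can
#' violate this reading, which is why shortlist entries are always labelled
#' candidates, never validated targets.
#'
#' @param direction Character vector over `{"up", "down"}`.
#' @return Character vector over `{"TF-activated", "TF-repressed"}`.
#' @export
infer_regulation_mode <- function(direction) {
  bad <- !direction %in% c("up", "down")
  if (any(bad)) {
    abort(sprintf(
      "direction must be 'up' or 'down' to infer a regulation mode (found '%s')",
      direction[bad][1]
    ))
  }
  ifelse(direction == "down", "TF-activated", "TF-repressed")
}

#' Intersect binding evidence with differential-expression evidence
#'
#' Produces one shortlist entry per gene that both carries a promoter
#' binding site (a row of [genes_with_binding()], optionally restricted by
#' biotype) and is significantly differentially expressed upon knockdown.
#' The primary join key is the version-stripped `gene_id`; for bound genes
#' whose id is absent from the DE table, a case-insensitive `gene_name`
#' fallback join can recover matches across annotation pipelines (logged).
#'
#' Entries are ordered for stable, report-ready output: upregulated genes
#' first in descending log2FC, then downregulated genes in ascending
#' log2FC.
#'
#' @param bound Tibble from [genes_with_binding()].
#' @param de Tibble with `gene_id`, `log2fc`, `padj`, `significant`,
#'   `direction` (see [apply_de_filters()]).
#' @param biotype Restrict the binding arm to this `biotype_class`
#'   (default `"lncRNA"`); use `"all"` for no restriction.
#' @param name_fallback Enable the case-insensitive gene-name fallback
#'   join (default `TRUE`).
#' @return Tibble of shortlist entries: `gene_id`, `gene_name`, `log2fc`,
#'   `padj`, `direction`, `regulation_mode`, `best_peak_score`,
#'   `distance_to_tss`.
#' @export
intersect_targets <- function(bound, de, biotype = "lncRNA",
                              name_fallback = TRUE) {
  if (!identical(biotype, "all") && "biotype_class" %in% names(bound)) {
    bound <- dplyr::filter(bound, .data$biotype_class == biotype)
  }
  sig <- dplyr::filter(de, .data$significant)

  hit <- inner_join(
    bound,
    sig[, c("gene_id", "log2fc", "padj", "direction")],
    by = "gene_id"
  )

  if (name_fallback && "gene_name" %in% names(sig)) {
    unmatched <- bound |>
      dplyr::filter(!.data$gene_id %in% hit$gene_id,
                    !is.na(.data$gene_name), nzchar(.data$gene_name))
    sig_by_name <- sig |>
      dplyr::filter(!.data$gene_id %in% bound$gene_id,
                    !is.na(.data$gene_name), nzchar(.data$gene_name)) |>
      mutate(name_key = tolower(.data$gene_name)) |>
      select("name_key", "log2fc", "padj", "direction")
    fallback <- unmatched |>
      mutate(name_key = tolower(.data$gene_name)) |>
      inner_join(sig_by_name, by = "name_key") |>
      select(-"name_key")
    if (nrow(fallback) > 0) {
      inform(sprintf("%d gene(s) joined by gene_name fallback", nrow(fallback)))
      hit <- bind_rows(hit, fallback)
    }
  }

  out <- hit |>
    mutate(regulation_mode = infer_regulation_mode(.data$direction)) |>
    select("gene_id", "gene_name", "log2fc", "padj", "direction",
           "regulation_mode", "best_peak_score", "distance_to_tss")
  up <- out |> dplyr::filter(.data$direction == "up") |> arrange(desc(.data$log2fc))
  down <- out |> dplyr::filter(.data$direction == "down") |> arrange(.data$log2fc)
  bind_rows(up, down)
}

#' Build the candidate-regulon integration report
#'
#' Collects the funnel of counts — bound genes by biotype, significant DE
#' genes by direction, and the final shortlist — together with the entries
#' themselves and the parameter snapshot. Every count is recomputed from
#' the sets passed in, never cached.
#'
#' @param bound Tibble from [genes_with_binding()].
#' @param de Filtered DE tibble (see [apply_de_filters()]).
#' @param shortlist Tibble from [intersect_targets()].
#' @param genes Optional annotation tibble; when given, the DE direction
#'   counts are restricted to lncRNA genes (matching the shortlist's
#'   biotype restriction), otherwise they cover all significant genes.
#' @param parameters Named list snapshot of the run configuration.
#' @return An object of class `regulon_report` with elements `counts`
#'   (named integer list), `entries` (the shortlist tibble) and
#'   `parameters`.
#' @export
summarize_integration <- function(bound, de, shortlist, genes = NULL,
                                  parameters = list()) {
  de_scope <- de
  if (!is.null(genes)) {
    lnc_ids <- genes$gene_id[genes$biotype_class == "lncRNA"]
    de_scope <- dplyr::filter(de, .data$gene_id %in% lnc_ids)
  }
  sig <- dplyr::filter(de_scope, .data$significant)
  counts <- list(
    n_bound_genes = nrow(bound),
    n_bound_coding = sum(bound$biotype_class == "coding"),
    n_bound_noncoding = sum(bound$biotype_class != "coding"),
    n_bound_lncRNA = sum(bound$biotype_class == "lncRNA"),
    n_de_lncRNA = nrow(sig),
    n_de_up = sum(sig$direction == "up"),
    n_de_down = sum(sig$direction == "down"),
    n_shortlist = nrow(shortlist),
    n_shortlist_up = sum(shortlist$direction == "up"),
    n_shortlist_down = sum(shortlist$direction == "down")
  )
  counts <- lapply(counts, as.integer)
  structure(
    list(counts = counts, entries = shortlist, parameters = parameters),
    class = "regulon_report"
  )
}

#' @export
print.regulon_report <- function(x, ...) {
  c_ <- x$counts
  cat("Candidate-regulon integration report\n")
  cat(sprintf("  bound genes: %d (coding %d / lncRNA %d / other %d)\n",
              c_$n_bound_genes, c_$n_bound_coding, c_$n_bound_lncRNA,
              c_$n_bound_noncoding - c_$n_bound_lncRNA))
  cat(sprintf("  significant DE (scope): %d (up %d / down %d)\n",
              c_$n_de_lncRNA, c_$n_de_up, c_$n_de_down))
  cat(sprintf("  shortlist: %d (up %d / down %d)\n",
              c_$n_shortlist, c_$n_shortlist_up, c_$n_shortlist_down))
  if (nrow(x$entries) > 0) {
    cat("\n")
    print(x$entries, n = 20)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the shortlist entries of a regulon report
#'
#' @param x A `regulon_report`.
#' @param ... Unused.
#' @return The shortlist entries as a tibble.
#' @exportS3Method generics::tidy
tidy.regulon_report <- function(x, ...) {
  as_tibble(x$entries)
}

#' One-row summary of a regulon report's count funnel
#'
#' @param x A `regulon_report`.
#' @param ... Unused.
#' @return A one-row tibble of the report counts.
#' @exportS3Method generics::glance
glance.regulon_report <- function(x, ...) {
  as_tibble(x$counts)
}

#' Fold-change bar chart of the shortlist
#'
#' Mirrors the standard presentation of a knockdown shortlist: one bar per
#' candidate gene, upregulated candidates in descending order of log2FC
#' followed by downregulated candidates in ascending order, coloured by
#' direction.
#'
#' @param object A `regulon_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regulon_report <- function(object, ...) {
  ent <- object$entries
  if (nrow(ent) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty shortlist"))
  }
  lab <- ifelse(nzchar(ent$gene_name), ent$gene_name, ent$gene_id)
  ent$label <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(ent, ggplot2::aes(x = .data$log2fc, y = .data$label,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#2166ac", down = "#b2182b")) +
    ggplot2::labs(x = "log2 fold change (knockdown / control)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# deterministic plain-list view used for JSON serialization
report_to_list <- function(report) {
  list(
    counts = report$counts,
    parameters = report$parameters,
    entries = lapply(seq_len(nrow(report$entries)), function(i) {
      as.list(report$entries[i, ])
    })
  )
}

#' Write a regulon report to JSON
#'
#' Deterministic serialization of the counts, parameter snapshot and
#' shortlist entries.
#'
#' @param report A `regulon_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}
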