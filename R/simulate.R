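#' Configuration for the coupled synthetic dataset
#'
#' Bundles and validates every knob of the synthetic generator. The
#' defaults emulate a desk-scale version of a TF-knockdown study: a toy
#' genome of 200 genes on 2 chromosomes (30% lncRNA), a quarter of the
#' genes carrying one promoter peak with scores well separated from decoy
#' background peaks, and a 3 vs 3 control/knockdown count design with a
#' planted |log2FC| of 2 on half of the bound lncRNAs (plus an equal
#' number of unbound confounders).
#'
#' @param seed Master seed; per-stage streams are derived from it, so each
#'   stage is individually reproducible.
#' @param n_chroms,chrom_length,n_genes Toy genome shape.
#' @param lncrna_fraction Fraction of genes annotated as lncRNA (exact
#'   quota, not sampled).
#' @param bound_fraction Fraction of genes given one promoter peak (quota).
#' @param n_decoy_peaks Background peaks placed at least `radius + 1` away
#'   from every TSS.
#' @param promoter_score_range,decoy_score_range Uniform ranges for the
#'   height/width score of planted and decoy peaks. The defaults are
#'   strictly separable (decoy maximum below promoter minimum), which is
#'   what makes exact end-to-end recovery well defined.
#' @param n_reps_per_group Replicates per condition (default 3, i.e. 3v3).
#' @param planted_lfc Absolute planted log2 fold change; signs alternate
#'   so both regulation modes are exercised.
#' @param planted_target_fraction Fraction of bound lncRNAs planted as DE.
#' @param mean_count_range Log-uniform range of baseline mean counts.
#' @param dispersion Negative-binomial dispersion of simulated counts.
#' @param promoter_radius Promoter half-width used for peak placement.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length = 1e6,
                              n_genes = 200L,
                              lncrna_fraction = 0.3,
                              bound_fraction = 0.25,
                              n_decoy_peaks = 100L,
                              promoter_score_range = c(50, 150),
                              decoy_score_range = c(1, 20),
                              n_reps_per_group = 3L,
                              planted_lfc = 2,
                              planted_target_fraction = 0.5,
                              mean_count_range = c(100, 2000),
                              dispersion = 0.05,
                              promoter_radius = 2000L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    lncrna_fraction = lncrna_fraction, bound_fraction = bound_fraction,
    n_decoy_peaks = as.integer(n_decoy_peaks),
    promoter_score_range = promoter_score_range,
    decoy_score_range = decoy_score_range,
    n_reps_per_group = as.integer(n_reps_per_group),
    planted_lfc = planted_lfc,
    planted_target_fraction = planted_target_fraction,
    mean_count_range = mean_count_range, dispersion = dispersion,
    promoter_radius = as.integer(promoter_radius)
  )
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes >= 1,
    cfg$lncrna_fraction > 0, cfg$lncrna_fraction < 1,
    cfg$bound_fraction > 0, cfg$bound_fraction < 1,
    cfg$planted_target_fraction > 0, cfg$planted_target_fraction < 1,
    length(cfg$promoter_score_range) == 2, all(cfg$promoter_score_range > 0),
    length(cfg$decoy_score_range) == 2, all(cfg$decoy_score_range > 0),
    cfg$dispersion > 0, all(cfg$mean_count_range > 0),
    cfg$promoter_radius > 0
  )
  structure(cfg, class = "sim_config")
}

# gene length bounds used by the annotation generator
SIM_GENE_LEN <- c(1000L, 4000L)

#' Simulate a toy gene annotation
#'
#' Places non-overlapping genes in equal slots along each chromosome, with
#' strands drawn Bernoulli(0.5) and an exact lncRNA quota
#' (`round(lncrna_fraction * n_genes)`). Each gene is kept at least
#' `promoter_radius + 1` away from its slot boundaries, so promoter
#' windows of neighbouring genes can never overlap — the property that
#' makes planted-peak recovery unambiguous. Deterministic given the
#' config seed; re-running writes byte-identical GTF.
#'
#' @param config A [simulation_config()].
#' @param gtf_path Optional path; when given the annotation is also
#'   written as GTF.
#' @return Gene tibble in the [read_gene_annotation()] layout.
#' @export
simulate_annotation <- function(config, gtf_path = NULL) {
  set.seed(stage_seed(config$seed, "annotation"))
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  margin <- config$promoter_radius + 1L
  rows <- list()
  idx <- 0L
  for (ci in seq_len(config$n_chroms)) {
    nc <- per_chrom[ci]
    if (nc == 0) next
    slot <- config$chrom_length %/% nc
    if (slot < SIM_GENE_LEN[2] + 2L * margin) {
      abort(sprintf(
        "cannot place %d genes on a chromosome of length %d without overlap (need slots of at least %d nt)",
        nc, config$chrom_length, SIM_GENE_LEN[2] + 2L * margin
      ))
    }
    len <- sample(SIM_GENE_LEN[1]:SIM_GENE_LEN[2], nc, replace = TRUE)
    off <- vapply(len, function(l) sample(margin:(slot - l - margin), 1L), 1L)
    start <- (seq_len(nc) - 1L) * slot + off
    rows[[ci]] <- tibble(
      chrom = paste0("chrS", ci),
      start = as.integer(start),
      end = as.integer(start + len),
      strand = ifelse(rbinom(nc, 1, 0.5) == 1, "+", "-")
    )
    idx <- idx + nc
  }
  genes <- bind_rows(rows)
  genes$gene_id <- sprintf("SYNG%04d", seq_len(nrow(genes)))
  genes$gene_name <- sprintf("Syn%04d", seq_len(nrow(genes)))
  n_lnc <- round(config$lncrna_fraction * n)
  lnc_idx <- sample(seq_len(n), n_lnc)
  genes$raw_biotype <- "protein_coding"
  genes$raw_biotype[lnc_idx] <- "lncRNA"
  genes$biotype_class <- classify_biotype(genes$raw_biotype)
  genes$tss <- compute_tss(genes)
  genes <- genes[, c("gene_id", "gene_name", "chrom", "start", "end",
                     "strand", "tss", "raw_biotype", "biotype_class")]
  if (!is.null(gtf_path)) write_gene_annotation(genes, gtf_path)
  genes
}

#' Simulate promoter peaks and background decoys
#'
#' A quota of `round(bound_fraction * n_genes)` genes (sampled without
#' replacement) each receive one peak whose summit is uniform within
#' `promoter_radius` of their TSS and whose height/width score is drawn
#' from `promoter_score_range`. Decoy peaks are placed at least
#' `promoter_radius + 1` nt away from every TSS, with scores from
#' `decoy_score_range`. Deterministic given the config seed.
#'
#' @param genes Tibble from [simulate_annotation()].
#' @param config A [simulation_config()].
#' @param peak_path Optional path; when given, peaks are written as ENCODE
#'   narrowPeak.
#' @return List: `peaks` (tibble in [read_peaks()] layout plus
#'   `summit_offset`), `truth` (tibble: `name`, `is_promoter_peak`,
#'   `target_gene_id`), `bound_gene_ids`.
#' @export
simulate_peaks <- function(genes, config, peak_path = NULL) {
  set.seed(stage_seed(config$seed, "peaks"))
  radius <- config$promoter_radius
  n_bound <- round(config$bound_fraction * nrow(genes))
  bound_idx <- sort(sample(nrow(genes), n_bound))

  make_peak <- function(summit, score_range) {
    width <- sample(200:400, 1L)
    score <- runif(1, score_range[1], score_range[2])
    start <- max(0L, as.integer(summit - width %/% 2L))
    list(start = start, end = start + width, width = width,
         height = score * width, summit_offset = as.integer(summit - start))
  }

  rows <- vector("list", n_bound + config$n_decoy_peaks)
  for (k in seq_along(bound_idx)) {
    g <- genes[bound_idx[k], ]
    summit <- max(1L, g$tss + sample((-radius):radius, 1L))
    p <- make_peak(summit, config$promoter_score_range)
    rows[[k]] <- tibble(
      chrom = g$chrom, start = p$start, end = p$end,
      name = sprintf("promoter_peak_%03d", k),
      height = p$height, width = p$width,
      summit_offset = p$summit_offset,
      is_promoter_peak = TRUE, target_gene_id = g$gene_id
    )
  }
  tss_by_chrom <- split(genes$tss, genes$chrom)
  chroms <- unique(genes$chrom)
  for (k in seq_len(config$n_decoy_peaks)) {
    placed <- FALSE
    for (try in 1:1000) {
      chrom <- chroms[sample(length(chroms), 1L)]
      summit <- sample(500:(config$chrom_length - 500L), 1L)
      if (all(abs(summit - tss_by_chrom[[chrom]]) >= radius + 1L)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place a decoy peak outside every promoter window after 1000 tries")
    }
    p <- make_peak(summit, config$decoy_score_range)
    rows[[n_bound + k]] <- tibble(
      chrom = chrom, start = p$start, end = p$end,
      name = sprintf("decoy_peak_%03d", k),
      height = p$height, width = p$width,
      summit_offset = p$summit_offset,
      is_promoter_peak = FALSE, target_gene_id = NA_character_
    )
  }
  peaks <- bind_rows(rows) |> arrange(.data$chrom, .data$start, .data$name)
  peaks$score <- peaks$height / peaks$width
  peaks$anchor <- as.integer(peaks$start + peaks$summit_offset)
  truth <- peaks[, c("name", "is_promoter_peak", "target_gene_id")]
  out <- peaks[, c("chrom", "start", "end", "name", "height", "width",
                   "score", "anchor", "summit_offset")]
  if (!is.null(peak_path)) {
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
      out$chrom, out$start, out$end, out$name,
      pmin(1000L, as.integer(round(out$height))),
      sprintf("%.4f", out$height), out$summit_offset
    )
    readr::write_lines(lines, peak_path)
  }
  list(
    peaks = out, truth = truth,
    bound_gene_ids = genes$gene_id[bound_idx]
  )
}

#' Simulate a control vs knockdown count matrix with planted fold changes
#'
#' Baseline means are log-uniform over `mean_count_range`. A quota of
#' `round(planted_target_fraction * n)` of the bound lncRNAs, plus an
#' equal number of unbound genes (confounders for specificity checks),
#' receive a knockdown mean of `baseline * 2^(s * planted_lfc)` with signs
#' alternating up/down; all counts are negative binomial with the
#' configured dispersion. Deterministic given the config seed.
#'
#' @param genes Tibble from [simulate_annotation()].
#' @param bound_gene_ids Character vector of bound genes (from
#'   [simulate_peaks()]).
#' @param config A [simulation_config()].
#' @param counts_path,conditions_path Optional output paths for the counts
#'   TSV and the sample condition map.
#' @return List: `counts` (a `count_matrix`), `truth` (tibble: `gene_id`,
#'   `is_lncRNA`, `is_bound`, `is_de`, `planted_log2fc`).
#' @export
simulate_counts <- function(genes, bound_gene_ids, config,
                            counts_path = NULL, conditions_path = NULL) {
  if (config$n_reps_per_group < 2) {
    abort("n_reps_per_group must be at least 2 for a testable design")
  }
  set.seed(stage_seed(config$seed, "counts"))
  n <- nrow(genes)
  baseline <- exp(runif(n, log(config$mean_count_range[1]),
                        log(config$mean_count_range[2])))
  is_bound <- genes$gene_id %in% bound_gene_ids
  is_lnc <- genes$biotype_class == "lncRNA"
  bound_lnc <- which(is_bound & is_lnc)
  n_targets <- round(config$planted_target_fraction * length(bound_lnc))
  targets <- sort(sample(bound_lnc, n_targets))
  unbound_pool <- which(!is_bound)
  confounders <- sort(sample(unbound_pool, min(n_targets, length(unbound_pool))))

  planted <- rep(0, n)
  planted[targets] <- rep(c(1, -1), length.out = length(targets)) * config$planted_lfc
  planted[confounders] <- rep(c(-1, 1), length.out = length(confounders)) * config$planted_lfc

  reps <- config$n_reps_per_group
  mu_c <- baseline
  mu_k <- baseline * 2^planted
  draw <- function(mu) rnbinom(n, mu = mu, size = 1 / config$dispersion)
  mat <- cbind(
    vapply(seq_len(reps), function(i) draw(mu_c), numeric(n)),
    vapply(seq_len(reps), function(i) draw(mu_k), numeric(n))
  )
  storage.mode(mat) <- "integer"
  colnames(mat) <- c(paste0("control_", seq_len(reps)),
                     paste0("knockdown_", seq_len(reps)))
  rownames(mat) <- genes$gene_id
  cond <- rep(c("control", "knockdown"), each = reps)
  cm <- structure(
    list(counts = mat,
         samples = tibble(sample_id = colnames(mat), condition = cond)),
    class = "count_matrix"
  )
  truth <- tibble(
    gene_id = genes$gene_id,
    is_lncRNA = is_lnc,
    is_bound = is_bound,
    is_de = planted != 0,
    planted_log2fc = planted
  )
  if (!is.null(counts_path)) {
    out <- as_tibble(mat)
    out <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), out)
    readr::write_tsv(out, counts_path, progress = FALSE)
  }
  if (!is.null(conditions_path)) {
    readr::write_tsv(cm$samples, conditions_path, progress = FALSE)
  }
  list(counts = cm, truth = truth)
}

#' Generate the full coupled synthetic dataset on disk
#'
#' Runs the three generators with one master seed and writes all fixture
#' files plus the ground-truth manifests into `dir`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `genes` tibble and
#'   the gene/peak `truth` tibbles.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gtf = file.path(dir, "genes.gtf"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    counts = file.path(dir, "counts.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_peaks = file.path(dir, "truth_peaks.tsv")
  )
  genes <- simulate_annotation(config, gtf_path = paths$gtf)
  pk <- simulate_peaks(genes, config, peak_path = paths$peaks)
  cnt <- simulate_counts(genes, pk$bound_gene_ids, config,
                         counts_path = paths$counts,
                         conditions_path = paths$conditions)
  readr::write_tsv(cnt$truth, paths$truth_genes, progress = FALSE)
  readr::write_tsv(pk$truth, paths$truth_peaks, progress = FALSE)
  invisible(list(paths = paths, genes = genes,
                 truth_genes = cnt$truth, truth_peaks = pk$truth))
}
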