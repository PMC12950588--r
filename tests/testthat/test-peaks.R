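test_that("narrowPeak parsing derives width, score and anchor as documented", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(c(
    np_line(start = 100, end = 400, signal = 600, summit = -1),
    np_line(start = 100, end = 400, name = "q", signal = 600, summit = 50),
    np_line(start = 0, end = 2, name = "r", signal = 210, summit = -1)
  ), path)
  p <- read_peaks(path, dialect = "narrowPeak")
  expect_equal(p$width, c(300L, 300L, 2L))
  expect_equal(p$score, c(2, 2, 105)) # height / width
  expect_equal(p$anchor[1], 250L) # no summit -> midpoint
  expect_equal(p$anchor[2], 150L) # summit offset 50 from start 100
  expect_equal(p$height, c(600, 600, 210))
})

test_that("peak dialect errors: bad intervals, missing height, short rows", {
  bad <- tempfile()
  writeLines(c(np_line(), "chr1\t500\t400\tx\t1\t.\t9\t-1\t-1\t-1"), bad)
  expect_error(read_peaks(bad), "line 2")

  bed3 <- tempfile()
  writeLines("chr1\t100\t400", bed3)
  expect_error(read_peaks(bed3, dialect = "bed"), "narrowPeak or 5-column BED")

  bed5 <- tempfile()
  writeLines("chr1\t100\t400\tp\t50", bed5)
  p <- read_peaks(bed5, dialect = "bed")
  expect_equal(p$height, 50)
  expect_equal(p$anchor, 250L)

  # height-column policy switches narrowPeak height between cols 7 and 5
  np <- tempfile()
  writeLines(np_line(score5 = 120, signal = 600), np)
  expect_equal(read_peaks(np)$height, 600)
  expect_equal(read_peaks(np, height_column = "score")$height, 120)
})

test_that("first-quartile threshold interpolates between order statistics", {
  expect_equal(quartile_threshold(c(1, 2, 3, 4)), 1.75)
  expect_equal(quartile_threshold(c(4, 1, 3, 2)), 1.75) # order-free
  expect_equal(quartile_threshold(c(5, 5, 5)), 5)
  expect_equal(quartile_threshold(7), 7)
  expect_error(quartile_threshold(numeric(0)), "empty")
})

test_that("background filter removes strictly-below-quartile peaks, keeps ties", {
  mk <- function(scores) tibble::tibble(
    chrom = "c1", start = seq_along(scores) * 1000L,
    end = seq_along(scores) * 1000L + 100L, name = paste0("p", seq_along(scores)),
    height = scores * 100, width = 100L, score = scores,
    anchor = seq_along(scores) * 1000L + 50L
  )
  kept <- filter_background(mk(c(1, 2, 3, 4)))
  expect_equal(kept$score, c(2, 3, 4))
  expect_equal(attr(kept, "threshold"), 1.75)
  expect_equal(nrow(attr(kept, "removed")), 1)

  allsame <- filter_background(mk(c(5, 5, 5)))
  expect_equal(nrow(allsame), 3) # nothing strictly below Q1

  none <- filter_background(mk(numeric(0)))
  expect_equal(nrow(none), 0)
  expect_true(is.na(attr(none, "threshold")))
})

test_that("filter conserves the input partition and is scale-equivariant", {
  for (seed in 1:10) {
    inst <- random_instance(n_peaks = 80, n_genes = 5, seed = seed)
    peaks <- inst$peaks
    kept <- filter_background(peaks)
    removed <- attr(kept, "removed")
    thr <- attr(kept, "threshold")
    expect_equal(nrow(kept) + nrow(removed), nrow(peaks))
    expect_true(all(kept$score >= thr))
    expect_true(all(removed$score < thr))
    # multiplying heights by c scales scores and threshold, partition unchanged
    scaled <- peaks
    scaled$height <- scaled$height * 7.3
    scaled$score <- scaled$height / scaled$width
    kept2 <- filter_background(scaled)
    expect_equal(kept2$name, kept$name)
    expect_equal(attr(kept2, "threshold"), thr * 7.3)
  }
})

test_that("promoter assignment matches the brute-force double loop exactly", {
  for (seed in 1:200) {
    n_peaks <- sample(0:60, 1)
    n_genes <- sample(1:25, 1)
    inst <- random_instance(n_peaks, n_genes, radius = 2000, seed = seed)
    got <- assign_to_promoters(inst$peaks, inst$windows)
    ref <- brute_force_assign(inst$peaks, inst$windows)
    key <- function(nm, gid, d) sort(paste(nm, gid, d))
    expect_equal(
      key(got$peak_name, got$gene_id, got$distance_to_tss),
      key(inst$peaks$name[ref$peak], ref$gene_id, ref$distance_to_tss)
    )
  }
  # a couple of larger instances at the documented bounds
  for (seed in 201:205) {
    inst <- random_instance(500, 200, seed = seed)
    got <- assign_to_promoters(inst$peaks, inst$windows)
    ref <- brute_force_assign(inst$peaks, inst$windows)
    expect_equal(nrow(got), nrow(ref))
  }
})

test_that("assignment boundaries, multi-hits and strand sign behave as specified", {
  windows <- tibble::tibble(
    gene_id = c("gplus", "gminus"), chrom = "c1",
    tss = c(10000L, 10000L), strand = c("+", "-"), radius = 2000L
  )
  mkpeak <- function(anchor) tibble::tibble(
    chrom = "c1", start = anchor - 50L, end = anchor + 50L, name = "p",
    height = 10, width = 100L, score = 0.1, anchor = as.integer(anchor)
  )
  a <- assign_to_promoters(mkpeak(9500), windows)
  expect_equal(nrow(a), 2) # equidistant from both TSSs -> two assignments
  expect_equal(a$distance_to_tss[a$gene_id == "gplus"], -500L) # upstream
  expect_equal(a$distance_to_tss[a$gene_id == "gminus"], 500L) # sign flipped
  expect_equal(nrow(assign_to_promoters(mkpeak(13000), windows)), 0)
  expect_equal(nrow(assign_to_promoters(mkpeak(12000), windows)), 2) # inclusive
})

test_that("mirroring coordinates and strands preserves pairs and oriented distances", {
  inst <- random_instance(100, 40, seed = 99)
  got <- assign_to_promoters(inst$peaks, inst$windows)
  L <- 60000L
  m_peaks <- inst$peaks
  m_peaks$anchor <- L - inst$peaks$anchor
  m_peaks$start <- L - inst$peaks$end
  m_peaks$end <- L - inst$peaks$start
  m_windows <- inst$windows
  m_windows$tss <- L - inst$windows$tss
  m_windows$strand <- ifelse(inst$windows$strand == "+", "-", "+")
  mirrored <- assign_to_promoters(m_peaks, m_windows)
  key <- function(d) sort(paste(d$peak_name, d$gene_id))
  expect_equal(key(mirrored), key(got))
  merged <- merge(
    got[, c("peak_name", "gene_id", "distance_to_tss")],
    mirrored[, c("peak_name", "gene_id", "distance_to_tss")],
    by = c("peak_name", "gene_id")
  )
  # the sign convention is gene-oriented (negative = upstream of the gene),
  # so reflecting the genome and flipping strands maps upstream to upstream:
  # signed distances are invariant, not negated
  expect_equal(merged$distance_to_tss.x, merged$distance_to_tss.y)
})

test_that("bound-gene summary dedups, picks best peaks and partitions biotypes", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), gene_name = c("a", "b"), chrom = "c1",
    start = c(1000L, 50000L), end = c(2000L, 51000L), strand = "+",
    raw_biotype = c("protein_coding", "lncRNA"),
    biotype_class = c("coding", "lncRNA")
  )
  genes$tss <- compute_tss(genes)
  asg <- tibble::tibble(
    peak_chrom = "c1", peak_start = c(500L, 900L, 1500L, 49500L),
    peak_end = c(700L, 1100L, 1700L, 49700L), peak_name = paste0("p", 1:4),
    peak_height = c(10, 50, 50, 20), peak_width = 200L,
    peak_score = c(0.05, 0.25, 0.25, 0.10),
    anchor = c(600L, 1000L, 1600L, 49600L),
    gene_id = c("A", "A", "A", "B"),
    distance_to_tss = c(-400L, 0L, 600L, -400L)
  )
  bound <- genes_with_binding(asg, genes)
  expect_equal(nrow(bound), 2)
  a <- bound[bound$gene_id == "A", ]
  expect_equal(a$n_peaks, 3L)
  # max score wins; tie broken by smaller |distance|
  expect_equal(a$best_peak_score, 0.25)
  expect_equal(a$distance_to_tss, 0L)
  expect_equal(attr(bound, "partition"),
               c(coding = 1L, lncRNA = 1L, other_noncoding = 0L))
  expect_error(
    genes_with_binding(dplyr::mutate(asg, gene_id = "nope"), genes),
    "unknown gene_id"
  )
})
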