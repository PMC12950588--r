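write_counts_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("count reading validates shape, integrality and condition labels", {
  mat <- matrix(rpois(20, 50), nrow = 5,
                dimnames = list(paste0("G", 1:5, ".", 1:5),
                                c("nc1", "nc2", "kd1", "kd2")))
  cond <- c(nc1 = "control", nc2 = "control", kd1 = "knockdown", kd2 = "knockdown")
  cm <- read_counts(write_counts_fixture(mat), cond)
  expect_s3_class(cm, "count_matrix")
  expect_equal(rownames(cm$counts), paste0("G", 1:5)) # versions stripped
  expect_equal(cm$samples$condition, unname(cond))

  # condition map can come from a sidecar file
  cpath <- tempfile()
  readr::write_tsv(tibble::tibble(sample_id = names(cond), condition = cond),
                   cpath, progress = FALSE)
  cm2 <- read_counts(write_counts_fixture(mat), cpath)
  expect_equal(cm2$counts, cm$counts)

  dup <- rbind(mat, mat[1, , drop = FALSE])
  rownames(dup)[6] <- "G1.9"
  expect_error(read_counts(write_counts_fixture(dup), cond), "duplicate")

  frac <- mat
  frac[1, 1] <- 3.7
  expect_error(read_counts(write_counts_fixture(frac), cond), "3.7")

  neg <- mat
  neg[2, 2] <- -1
  expect_error(read_counts(write_counts_fixture(neg), cond), "non-negative")
})

test_that("median-of-ratios size factors match hand values and DESeq2", {
  mat <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2,
                dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_equal(unname(size_factors(mat)), c(1, 1))

  doubled <- mat
  doubled[, 2] <- mat[, 1] * 2
  sf <- size_factors(doubled)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2))) # rescaled to geomean 1

  expect_equal(unname(size_factors(mat[, 1, drop = FALSE])), 1)

  withzero <- mat # one zero in every gene row, but positive column sums
  withzero[1:2, 1] <- 0
  withzero[3:4, 2] <- 0
  expect_error(size_factors(withzero), "total")
  expect_silent(size_factors(withzero, method = "total"))

  # one sample scaled by c gets factor scaled by c (up to common rescaling)
  set.seed(3)
  big <- matrix(rpois(600, 200), ncol = 6)
  scaled <- big
  scaled[, 4] <- scaled[, 4] * 5L
  r <- size_factors(scaled) / size_factors(big)
  expect_equal(unname(r[4] / r[1]), 5, tolerance = 1e-6)

  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(big)
  mine <- size_factors(big)
  # agreement up to one common rescaling; DESeq2 takes the median on the log
  # scale, which differs in the 7th digit when averaging two middle ratios
  expect_equal(unname(mine / ref), rep(mean(mine / ref), 6), tolerance = 1e-5)
})

test_that("NB Wald stand-in recovers fold changes and flags all-zero genes", {
  set.seed(21)
  m <- 600
  shifted <- 2:61 # a 10% subset at exactly twice the control mean
  mu <- rep(500, m)
  mu_k <- mu
  mu_k[shifted] <- 2 * mu[shifted]
  counts <- cbind(
    matrix(rnbinom(3 * m, mu = mu, size = 20), ncol = 3),
    matrix(rnbinom(3 * m, mu = mu_k, size = 20), ncol = 3)
  )
  rownames(counts) <- paste0("g", 1:m)
  counts[1, ] <- 0L
  res <- nb_wald_test(counts, rep(c("control", "knockdown"), each = 3))
  expect_true(is.na(res$pvalue[1])) # all-zero gene: no test
  expect_equal(median(res$log2fc[shifted]), 1, tolerance = 0.1)
  expect_equal(median(res$log2fc[-c(1, shifted)]), 0, tolerance = 0.1)
  expect_error(nb_wald_test(counts, rep("control", 6)), "per condition")
})

test_that("NB Wald stand-in holds its type-I error on a planted null", {
  set.seed(2024)
  m <- 2000
  mu <- exp(runif(m, log(20), log(2000)))
  counts <- matrix(rnbinom(6 * m, mu = rep(mu, 6), size = 1 / 0.1), ncol = 6)
  rownames(counts) <- paste0("g", 1:m)
  res <- nb_wald_test(counts, rep(c("control", "knockdown"), each = 3))
  frac <- mean(res$pvalue < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.5, NA, 0.5)), c(0.5, NA, 0.5)) # m = 2 passthrough
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # hand-rolled step-up as an independent oracle on random inputs
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- pmin(1, cummin((p[o] * n / seq_len(n))[n:1])[n:1])
    out <- numeric(n)
    out[o] <- adj
    out
  }
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up(p))
    expect_true(all(adj >= p)) # never below the raw p
    expect_true(all(diff(adj[order(p)]) >= 0)) # monotone in the order stats
  }
  # idempotence on the tied worked example
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("significance filters implement strict alpha and inclusive lfc", {
  res <- tibble::tibble(
    gene_id = c("up_strong", "down_strong", "weak_fc", "exact_fc",
                "exact_alpha", "no_padj"),
    log2fc = c(1.190768343, -2.310831734, 0.4, 0.5, 2, 3),
    padj = c(0.001, 0.001, 0.001, 0.049, 0.05, NA)
  )
  out <- apply_de_filters(res)
  expect_equal(out$significant,
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction,
               c("up", "down", "none", "up", "none", "none"))
  # |up| + |down| = |significant|
  expect_equal(sum(out$direction != "none"), sum(out$significant))
})

test_that("external DE tables are parsed with NA handling and named-column errors", {
  path <- tempfile()
  writeLines(c(
    "gene_id\tlog2fc\tpvalue\tpadj\textra",
    "ENSG1.4\t1.5\t0.001\t0.01\tx",
    "ENSG2\t-0.2\t0.5\tNA\ty",
    "ENSG3\t0.8\t\t\tz"
  ), path)
  de <- read_de_table(path)
  expect_equal(de$gene_id, c("ENSG1", "ENSG2", "ENSG3"))
  expect_equal(is.na(de$padj), c(FALSE, TRUE, TRUE))
  expect_false("extra" %in% names(de))

  bad <- tempfile()
  writeLines(c("gene_id\tpvalue\tpadj", "g\t0.1\t0.2"), bad)
  expect_error(read_de_table(bad), "log2fc")
})
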