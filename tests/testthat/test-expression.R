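test_that("median-of-ratios size factors: closed forms and DESeq2 agreement", {
  # identical samples -> all factors 1
  m <- matrix(rep(c(10, 200, 3000), 4), ncol = 4,
              dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))
  # a sample duplicated with every count doubled gets a doubled factor
  set.seed(21)
  counts <- matrix(rnbinom(600, mu = 300, size = 10), ncol = 6)
  counts2 <- cbind(counts, counts[, 1] * 2)
  sf <- size_factors(counts2)
  expect_equal(sf[7] / sf[1], 2, tolerance = 1e-12)
  # genes with a zero are excluded from the reference set
  cz <- counts
  cz[5, 3] <- 0
  expect_equal(unname(size_factors(cz)),
               unname(apply(cz, 2, function(x)
                 exp(median((log(x) - rowMeans(log(cz)))[
                   is.finite(rowMeans(log(cz)))])))))
  # independent oracle: DESeq2's implementation
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-10)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("normalization is scale invariant up to a global constant", {
  set.seed(22)
  counts <- matrix(rnbinom(500, mu = 200, size = 10), ncol = 5,
                   dimnames = list(NULL, paste0("s", 1:5)))
  norm1 <- normalize_counts(counts, size_factors(counts))
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7
  norm2 <- normalize_counts(scaled, size_factors(scaled))
  # the classic (unrescaled) median-of-ratios definition reacts to scaling
  # one library by a single global constant on all normalized counts ...
  ratio <- norm2 / norm1
  expect_equal(max(ratio, na.rm = TRUE), min(ratio, na.rm = TRUE),
               tolerance = 1e-10)
  # ... so fold changes and cluster calls are exactly invariant
  meta <- data.frame(sample = colnames(counts),
                     time_h = c(0, 0, 6, 6, 6), replicate = c(1, 2, 1, 2, 3))
  expect_equal(expression_profiles(norm2, meta, pseudocount = 0)$log2fc,
               expression_profiles(norm1, meta, pseudocount = 0)$log2fc,
               tolerance = 1e-9)
  expect_error(normalize_counts(counts, rep(-1, 5)), "> 0")
  expect_equal(normalize_counts(counts, rep(1, 5)), counts)
})

test_that("log2 fold-change arithmetic with pseudocount", {
  counts <- rbind(flat = c(100, 100, 100, 100),
                  x4 = c(100, 100, 400, 400),
                  from0 = c(0, 0, 15, 15))
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  meta <- data.frame(sample = colnames(counts), time_h = c(0, 0, 6, 6),
                     replicate = c(1, 2, 1, 2))
  prof <- expression_profiles(counts, meta)
  fc <- setNames(prof$log2fc, prof$gene_id)
  expect_equal(fc[["flat"]], 0)
  expect_equal(fc[["x4"]], log2(401 / 101))  # ~2 for counts >> pseudocount
  expect_equal(fc[["from0"]], 4)             # log2((15+1)/(0+1))
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
    adj
  }
  set.seed(31)
  for (i in 1:500) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))  # independent oracle
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("stand-in location test: null calibration and power", {
  set.seed(41)
  n_genes <- 1000
  counts <- matrix(rnbinom(n_genes * 10, mu = 500, size = 1 / 0.05),
                   ncol = 10, dimnames = list(NULL, paste0("s", 1:10)))
  meta <- data.frame(sample = colnames(counts),
                     time_h = rep(c(0, 6), each = 5),
                     replicate = rep(1:5, 2))
  prof <- expression_profiles(normalize_counts(counts,
                                               size_factors(counts)), meta)
  typeI <- mean(prof$pvalue < 0.05)
  expect_gt(typeI, 0.03)
  expect_lt(typeI, 0.07)
  # planted 8-fold change, n = 5, low dispersion -> detected >= 90%
  up <- matrix(rnbinom(200 * 10, mu = rep(c(500, 4000), each = 5 * 200),
                       size = 1 / 0.01), nrow = 200)
  colnames(up) <- paste0("s", 1:10)
  prof_up <- expression_profiles(up, meta)
  expect_gte(mean(prof_up$pvalue < 0.05), 0.9)
  # identical groups give p = 1
  const <- matrix(100, 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  expect_true(all(expression_profiles(const, meta)$pvalue >= 0.99))
  # single replicate -> p = 1, flagged
  meta1 <- data.frame(sample = c("s1", "s6"), time_h = c(0, 6),
                      replicate = 1)
  p1 <- expression_profiles(counts[, c(1, 6)], meta1)
  expect_true(all(p1$pvalue == 1))
  expect_true(all(p1$underpowered))
})

test_that("four-way classification thresholds and significance gate", {
  prof <- rbind(
    data.frame(gene_id = "strong", time_h = c(6, 12, 18, 24),
               mean_ref = 100, mean_t = 100,
               log2fc = c(0.2, 2.3, 2.9, 3.0), pvalue = 0.001, padj = 0.01),
    data.frame(gene_id = "mild", time_h = c(6, 12, 18, 24),
               mean_ref = 100, mean_t = 100,
               log2fc = c(0.1, 0.5, 1.4, 1.2), pvalue = 0.001, padj = 0.01),
    data.frame(gene_id = "gated", time_h = c(6, 12, 18, 24),
               mean_ref = 100, mean_t = 100,
               log2fc = c(1.8, 0, 0, 0), pvalue = 0.2,
               padj = c(0.2, 0.9, 0.9, 0.9)),
    data.frame(gene_id = "dn", time_h = c(6, 12, 18, 24),
               mean_ref = 100, mean_t = 100,
               log2fc = c(-1.2, -2.5, -0.2, 0), pvalue = 0.001, padj = 0.01),
    data.frame(gene_id = "both", time_h = c(6, 12, 18, 24),
               mean_ref = 100, mean_t = 100,
               log2fc = c(-1.5, 2.5, 0, 0), pvalue = 0.001, padj = 0.01))
  cl <- classify_expression(prof)
  get <- function(g) cl[cl$gene_id == g, ]
  expect_equal(get("strong")$cluster, "strong_up")
  expect_equal(get("strong")$deciding_log2fc, 3.0)
  expect_equal(get("mild")$cluster, "up")
  expect_equal(get("gated")$cluster, "unchanged")
  expect_equal(get("dn")$cluster, "down")
  expect_equal(get("dn")$deciding_log2fc, -2.5)
  # mixed gene: larger |log2FC| wins, flagged
  expect_equal(get("both")$cluster, "strong_up")
  expect_true(get("both")$mixed)
})

test_that("raising alpha never moves a regulated gene to unchanged", {
  set.seed(51)
  w <- simulate_world(sim_config(seed = 51, n_units = 8,
                                 n_filler_genes = 100L))
  prof <- expression_profiles(
    normalize_counts(w$counts, size_factors(w$counts)), w$metadata)
  strict <- classify_expression(prof, alpha = 0.01)
  loose <- classify_expression(prof, alpha = 0.10)
  moved <- strict$cluster != "unchanged" & loose$cluster == "unchanged"
  expect_false(any(moved))
  # labels partition the genes
  expect_true(all(strict$cluster %in%
                    c("strong_up", "up", "down", "unchanged")))
  expect_equal(anyDuplicated(strict$gene_id), 0)
})
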