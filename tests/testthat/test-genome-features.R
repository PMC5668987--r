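test_that("per-gene replication timing follows the bp-weighted formula", {
  gene <- tibble::tibble(gene_id = "g1", chrom = "c1", start = 1001,
                         end = 2000, tss = 1001)
  segs <- tibble::tibble(chrom = "c1",
                         start = c(600, 1400), end = c(1400, 3000),
                         value = c(0.2, 0.8))
  # 400 bp at 0.2 plus 600 bp at 0.8 over a 1000 bp gene.
  rt <- replication_timing_per_gene(gene, segs)
  expect_equal(rt$R_gene, (0.2 * 400 + 0.8 * 600) / 1000)
  expect_equal(rt$R_gene, 0.56)

  # Gene fully inside one segment: identity.
  one <- tibble::tibble(chrom = "c1", start = 0, end = 1e5, value = 0.37)
  expect_equal(replication_timing_per_gene(gene, one)$R_gene, 0.37)

  # Uncovered basepairs count as zero in the numerator, full length in the
  # denominator; renormalize mode divides by covered length only.
  half <- tibble::tibble(chrom = "c1", start = 1000, end = 1500,
                         value = 0.6)
  expect_equal(replication_timing_per_gene(gene, half)$R_gene,
               0.6 * 500 / 1000)
  expect_equal(replication_timing_per_gene(gene, half,
                                           uncovered = "renormalize")$R_gene,
               0.6)
  # Zero covered basepairs: missing.
  far <- tibble::tibble(chrom = "c1", start = 5e5, end = 6e5, value = 0.9)
  expect_true(is.na(replication_timing_per_gene(gene, far)$R_gene))

  # Overlapping segments violate the track invariant.
  bad <- tibble::tibble(chrom = "c1", start = c(0, 500), end = c(600, 900),
                        value = c(0.1, 0.2))
  expect_error(replication_timing_per_gene(gene, bad), "overlap")

  # Splitting a segment into contiguous equal-value pieces changes nothing.
  split2 <- tibble::tibble(chrom = "c1", start = c(600, 1000, 1400, 2100),
                           end = c(1000, 1400, 2100, 3000),
                           value = c(0.2, 0.2, 0.8, 0.8))
  expect_equal(replication_timing_per_gene(gene, split2)$R_gene, 0.56)
})

test_that("bp-weighted timing equals the per-basepair brute force", {
  set.seed(13)
  for (i in 1:20) {
    gstart <- sample(1:500, 1)
    gene <- tibble::tibble(gene_id = "g", chrom = "c1", start = gstart,
                           end = gstart + sample(50:300, 1), tss = gstart)
    bounds <- sort(sample(0:1000, sample(3:8, 1)))
    segs <- tibble::tibble(chrom = "c1", start = bounds[-length(bounds)],
                           end = bounds[-1],
                           value = round(runif(length(bounds) - 1), 3))
    segs <- segs[segs$start < segs$end, ]
    keep <- sample(nrow(segs), max(1, nrow(segs) - 2))
    segs <- segs[sort(keep), ]
    expected <- rt_bruteforce(gene, segs)
    got <- replication_timing_per_gene(gene, segs)$R_gene
    if (is.na(expected)) expect_true(is.na(got))
    else expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("single-term entropy matches its closed forms", {
  expect_equal(tad_entropy_value(1), 0)
  expect_equal(tad_entropy_value(0), 0)
  expect_equal(tad_entropy_value(0.5), 0.5 * log(2))
  expect_equal(tad_entropy_value(1 / exp(1)), 1 / exp(1))
  # 1/e is the maximum under the natural log.
  p <- seq(0, 1, by = 1e-4)
  expect_true(all(tad_entropy_value(p) <= 1 / exp(1) + 1e-12))
  expect_true(all(tad_entropy_value(p) >= 0))
  # Binary mode gives the standard two-term entropy.
  expect_equal(tad_entropy_value(0.5, binary = TRUE), log(2))
  expect_error(tad_entropy_value(1.2), "0, 1")
})

test_that("TAD entropy assigns genes by TSS and partitions them", {
  tads <- tibble::tibble(chrom = "c1", start = c(0, 1e4, 2e4),
                         end = c(1e4, 2e4, 3e4),
                         tad_id = c("T1", "T2", "T3"))
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6), chrom = "c1",
    start = c(100, 5000, 10100, 15000, 20100, 40100),
    end = c(1100, 6000, 11100, 16000, 21100, 41100),
    tss = c(100, 5000, 10100, 15000, 20100, 40100))
  out <- tad_entropy(tads, genes, sexbiased = c("g1", "g3", "g4"))
  expect_equal(out$n_genes, c(2L, 2L, 1L))
  expect_equal(out$n_sexbiased, c(1L, 2L, 0L))
  expect_equal(out$p, c(0.5, 1, 0))
  expect_equal(out$entropy, c(0.5 * log(2), 0, 0))
  expect_equal(out$contains_sexbiased, c(TRUE, TRUE, FALSE))
  # g6 has its TSS beyond every TAD.
  expect_equal(attr(out, "n_unassigned"), 1L)
  # Each assignable gene falls in exactly one TAD.
  expect_equal(sum(out$n_genes), 5L)

  over <- tibble::tibble(chrom = "c1", start = c(0, 5e3), end = c(1e4, 2e4))
  expect_error(tad_entropy(over, genes, "g1"), "overlap")
})

test_that("timing-vs-bias regressions recover planted structure", {
  set.seed(17)
  n <- 1000
  de <- tibble::tibble(gene_id = sprintf("g%04d", 1:n),
                       log2fc = rnorm(n),
                       bias = sample(c("unbiased", "female", "male"), n,
                                     replace = TRUE))
  # Exact linear relation.
  timing <- tibble::tibble(gene_id = de$gene_id,
                           R_gene = 2 * de$log2fc + 0.3)
  fit <- suppressWarnings(
    regress_timing_on_bias(timing, de, mode = "continuous"))
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["log2fc"]), 2, tolerance = 1e-10)
  expect_equal(unname(est["(Intercept)"]), 0.3, tolerance = 1e-10)

  # Equal group means: category coefficients vanish (n divisible by 6 so
  # the alternating response averages to exactly 0.5 in every group).
  m6 <- 996
  de_j <- de[1:m6, ]
  de_j$bias <- rep(c("unbiased", "female", "male"), length.out = m6)
  timing_eq <- tibble::tibble(
    gene_id = de_j$gene_id,
    R_gene = rep(c(0.4, 0.6), length.out = m6))
  fit3 <- regress_timing_on_bias(timing_eq, de_j, mode = "categorical")
  est3 <- setNames(fit3$estimate, fit3$term)
  expect_equal(unname(est3["biasfemale"]), 0, tolerance = 1e-10)
  expect_equal(unname(est3["biasmale"]), 0, tolerance = 1e-10)
  expect_s3_class(attr(fit3, "f_test"), "tbl_df")

  # Planted slope recovered within 3 standard errors.
  timing_n <- tibble::tibble(gene_id = de$gene_id,
                             R_gene = 0.3 * de$log2fc + rnorm(n, 0, 0.05))
  fit4 <- regress_timing_on_bias(timing_n, de, mode = "continuous")
  sl <- fit4[fit4$term == "log2fc", ]
  expect_lt(abs(sl$estimate - 0.3), 3 * sl$se)
})
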