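test_that("cohort generator is reproducible and validates its parameters", {
  spec <- cohort_spec(n_samples = 8, n_silent_genes = 20,
                      n_escape_genes = 5, seed = 1)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)

  # Per-sample sub-streams: adding samples leaves existing ones untouched.
  bigger <- simulate_cohort(cohort_spec(n_samples = 12, n_silent_genes = 20,
                                        n_escape_genes = 5, seed = 1))
  expect_identical(a$sites, bigger$sites[bigger$sites$sample_id %in%
                                           a$sites$sample_id, ])

  expect_true(all(a$truth$samples$theta >= 0.5 &
                    a$truth$samples$theta < 1))
  expect_true(all(a$sites$major_count <= a$sites$total_count))
  expect_true(all(a$sites$major_count >=
                    a$sites$total_count - a$sites$major_count))
  # Sites lie inside their gene's interval.
  ann <- a$truth$annotation
  joined <- merge(a$sites, ann, by = "gene_id")
  expect_true(all(joined$pos >= joined$start & joined$pos <= joined$end))

  expect_error(cohort_spec(clonality_alpha = 0), "clonality_alpha")
  expect_error(cohort_spec(clonality_beta = -1), "clonality_beta")
  expect_error(cohort_spec(n_samples = 0), "n_samples")
  expect_error(cohort_spec(escape_ratio_mean = 0.4), "escape_ratio_mean")
})

test_that("degenerate no-escape cohort concentrates at the clonal skew", {
  # Near-degenerate Beta (alpha, beta scaled up) pins theta ~ 0.85 for
  # every sample; silent-gene ratios then match theta within binomial
  # error at high coverage.
  spec <- cohort_spec(n_samples = 10, n_silent_genes = 30,
                      n_escape_genes = 0, coverage_mean = 1e4,
                      clonality_alpha = 7e6, clonality_beta = 3e6,
                      seed = 2)
  co <- simulate_cohort(spec)
  expect_equal(unname(co$truth$samples$theta), rep(0.85, 10),
               tolerance = 1e-3)
  per_gene <- tapply(co$sites$major_count / co$sites$total_count,
                     co$sites$gene_id, mean)
  expect_true(all(abs(per_gene - 0.85) < 0.01))
})

test_that("escape-gene allele fractions are balanced on average", {
  spec <- cohort_spec(n_samples = 100, n_silent_genes = 50,
                      n_escape_genes = 30, coverage_mean = 50,
                      escape_ratio_mean = 0.5, seed = 3)
  co <- simulate_cohort(spec)
  esc_genes <- co$truth$genes$gene_id[co$truth$genes$escape]
  esc_sites <- co$sites[co$sites$gene_id %in% esc_genes, ]
  # The raw haplotype fraction is the simulated Binomial(cov, 0.5) draw.
  expect_equal(mean(esc_sites$hap_count / esc_sites$total_count), 0.5,
               tolerance = 0.02)
  # Silent sites are skewed well away from 0.5.
  sil_sites <- co$sites[!co$sites$gene_id %in% esc_genes, ]
  expect_gt(mean(sil_sites$major_count / sil_sites$total_count), 0.75)
})

test_that("genome generator emits consistent tracks", {
  spec <- genome_spec(n_genes = 60, chrom_lengths = c(c1 = 5e6, c2 = 3e6),
                      n_tfs = 4, enriched_tf_ids = "TF01",
                      n_sites_per_tf = 100, tad_size_mean = 5e5, seed = 4)
  g <- simulate_genome(spec, target_gene_set = 1:10)
  expect_identical(g, simulate_genome(spec, target_gene_set = 1:10))

  lens <- c(c1 = 5e6, c2 = 3e6)
  for (tr in list(g$tfbs, g$replication, g$tads)) {
    expect_true(all(tr$start >= 0 & tr$start < tr$end))
    expect_true(all(tr$end <= lens[tr$chrom]))
  }
  # TSS inside the gene interval.
  expect_true(all(g$annotation$tss >= g$annotation$start &
                    g$annotation$tss <= g$annotation$end))
  # TADs tile each chromosome exactly.
  for (ch in names(lens)) {
    td <- g$tads[g$tads$chrom == ch, ]
    expect_equal(td$start, c(0, td$end[-nrow(td)]))
    expect_equal(td$end[nrow(td)], unname(lens[ch]))
  }
  # Replication segments are disjoint.
  expect_true(all(GenomicRanges::isDisjoint(
    GenomicRanges::GRanges(g$replication$chrom,
                           IRanges::IRanges(g$replication$start + 1,
                                            g$replication$end)))))

  # tad_size_mean equal to the chromosome length gives one TAD each.
  one <- simulate_genome(genome_spec(n_genes = 10,
                                     chrom_lengths = c(c1 = 2e6),
                                     tad_size_mean = 2e6, seed = 5))
  expect_equal(nrow(one$tads), 1L)

  expect_error(genome_spec(chrom_lengths = c(c1 = 1e3),
                           proximal_window = 2000), "window")
})

test_that("covariate simulator plants an exactly recoverable structure", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:300))
  cov0 <- simulate_covariates(genes, noise_sd = 0, seed = 6)
  expect_true(all(cov0$breadth >= 1 & cov0$breadth <= 56))
  expect_true(all(cov0$dnds >= 0))

  planted <- covariate_coefficients()
  fit <- suppressWarnings(fit_dnds_model(cov0))
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["regionXCR"]), planted$dnds[["region_XCR"]],
               tolerance = 1e-8)
  expect_equal(unname(est["xy_pairTRUE"]), planted$dnds[["xy_pair"]],
               tolerance = 1e-8)
  expect_equal(unname(est["escape_statusescape"]),
               planted$dnds[["escape"]], tolerance = 1e-8)

  fitb <- suppressWarnings(fit_breadth_model(cov0))
  estb <- setNames(fitb$estimate, fitb$term)
  expect_equal(unname(estb["biasfemale"]),
               planted$breadth[["bias_female"]], tolerance = 1e-8)
  expect_equal(unname(estb["dnds"]), planted$breadth[["dnds"]],
               tolerance = 1e-8)

  covi <- simulate_covariates(genes, noise_sd = 0, integer_breadth = TRUE,
                              seed = 6)
  expect_true(all(covi$breadth == round(covi$breadth)))

  expect_error(simulate_covariates(genes, noise_sd = -1), "noise_sd")
})
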