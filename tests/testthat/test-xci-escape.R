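test_that("clonality null estimates per-sample mean and spread", {
  mk_sites <- function(ratios, sample = "S1") tibble::tibble(
    sample_id = sample, chrom = "chrX", pos = seq_along(ratios),
    gene_id = sprintf("sil%02d", seq_along(ratios)),
    major_count = round(ratios * 1000), total_count = 1000)

  # Degenerate spread is floored at sigma_min.
  null <- fit_clonality_null(mk_sites(c(0.9, 0.9, 0.9)),
                             sprintf("sil%02d", 1:3), min_null_obs = 3)
  expect_equal(null$mu, 0.9)
  expect_equal(null$sigma, 0.01)

  # Two-point standard deviation.
  null2 <- fit_clonality_null(mk_sites(c(0.8, 1.0)),
                              sprintf("sil%02d", 1:2), min_null_obs = 2)
  expect_equal(null2$mu, 0.9)
  expect_equal(null2$sigma, sd(c(0.8, 1.0)), tolerance = 1e-12)

  # Too few observations: unusable, no parameters.
  nullu <- fit_clonality_null(mk_sites(c(0.8, 1.0)),
                              sprintf("sil%02d", 1:2), min_null_obs = 10)
  expect_false(nullu$usable)
  expect_true(is.na(nullu$mu))

  # Monoclonal synthetic sample: theta = 0.95, coverage 1000, 50 silent
  # sites; binomial concentration pins mu within 0.01.
  set.seed(7)
  cov <- rep(1000, 50)
  k <- rbinom(50, cov, 0.95)
  mono <- tibble::tibble(sample_id = "S1", chrom = "chrX", pos = 1:50,
                         gene_id = sprintf("sil%02d", 1:50),
                         major_count = pmax(k, cov - k), total_count = cov)
  nullm <- fit_clonality_null(mono, sprintf("sil%02d", 1:50))
  expect_equal(nullm$mu, 0.95, tolerance = 0.01)
})

test_that("per-sample gene test standardises against the null", {
  null <- toy_null(mu = 0.9, sigma = 0.05)
  mk <- function(ratio) tibble::tibble(
    sample_id = "S1", chrom = "chrX", pos = 1, gene_id = "g1",
    major_count = round(ratio * 1000), total_count = 1000)

  # Plain-normal lower-tail mode reproduces the closed forms.
  at_mu <- test_gene_sample(mk(0.9), null, sided = "lower",
                            null_dist = "normal")
  expect_equal(at_mu$z, 0)
  expect_equal(at_mu$p, 0.5)
  expect_false(at_mu$escape_flag)

  far <- test_gene_sample(mk(0.5), null, sided = "lower",
                          null_dist = "normal")
  expect_equal(far$z, -8)
  expect_equal(far$p, pnorm(-8))
  expect_equal(far$p, 6.22e-16, tolerance = 1e-2)
  expect_true(far$escape_flag)

  near <- test_gene_sample(mk(0.85), null, sided = "lower",
                           null_dist = "normal")
  expect_equal(near$z, -1)
  expect_equal(near$p, pnorm(-1), tolerance = 1e-12)
  expect_false(near$escape_flag)

  # Two-sided default: same z, doubled tail.
  two <- test_gene_sample(mk(0.85), null, null_dist = "normal")
  expect_equal(two$p, 2 * pnorm(-1), tolerance = 1e-12)

  # Unusable null: no call emitted (distinct from a silent call).
  bad_null <- toy_null()
  bad_null$usable <- FALSE
  expect_equal(nrow(test_gene_sample(mk(0.5), bad_null)), 0L)

  # Coverage weighting: two sites of unequal depth.
  two_sites <- tibble::tibble(
    sample_id = "S1", chrom = "chrX", pos = 1:2, gene_id = "g1",
    major_count = c(90, 30), total_count = c(100, 50))
  w <- test_gene_sample(two_sites, null)
  expect_equal(w$ratio, (0.9 * 100 + 0.6 * 50) / 150)
  u <- test_gene_sample(two_sites, null, weighting = "unweighted")
  expect_equal(u$ratio, 0.75)
})

test_that("lower-tail escape calls are monotone in the aggregated ratio", {
  null <- toy_null(mu = 0.88, sigma = 0.04)
  ratios <- seq(0.5, 1, by = 0.01)
  mk <- function(r) tibble::tibble(
    sample_id = "S1", chrom = "chrX", pos = 1, gene_id = "g1",
    major_count = round(r * 10000), total_count = 10000)
  flags <- vapply(ratios, function(r)
    test_gene_sample(mk(r), null, sided = "lower")$escape_flag, logical(1))
  # Once not-escape as the ratio rises, never escape again above it.
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("population aggregation applies the strict cutoff and data floor", {
  mk_calls <- function(n_escape, n_total) tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_total)), gene_id = "g1",
    ratio = 0.7, n_sites = 1L, z = 0, p = 0.5,
    escape_flag = c(rep(TRUE, n_escape), rep(FALSE, n_total - n_escape)))
  expect_equal(aggregate_population(mk_calls(4, 10))$population_call,
               "escape")       # 0.40 > 0.30
  expect_equal(aggregate_population(mk_calls(3, 10))$population_call,
               "silent")       # 0.30 is not > 0.30
  expect_equal(aggregate_population(mk_calls(4, 4))$population_call,
               "insufficient_data")  # fewer than 5 informative samples
})

test_that("ROC calibration reproduces closed forms and matches pROC", {
  # Perfect separation.
  fr <- c(e1 = 0.9, e2 = 0.85, s1 = 0, s2 = 0.05)
  roc <- roc_calibrate(fr, known_escape = c("e1", "e2"),
                       known_silent = c("s1", "s2"))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$misclassification, 0)

  # Single-cutoff grid worked example.
  r1 <- roc_calibrate(c(e = 0.4, s = 0.2), "e", "s", grid = 0.3)
  expect_equal(r1$curve$sensitivity, 1)
  expect_equal(r1$curve$specificity, 1)
  expect_equal(r1$curve$youden, 1)

  # Overlapping classes: AUC near 1/2, and equal to the Mann-Whitney AUC
  # computed independently by pROC on a dense grid.
  set.seed(11)
  esc <- round(runif(200), 2)
  sil <- round(runif(200), 2)
  fr2 <- setNames(c(esc, sil),
                  c(sprintf("e%03d", 1:200), sprintf("s%03d", 1:200)))
  roc2 <- roc_calibrate(fr2, sprintf("e%03d", 1:200),
                        sprintf("s%03d", 1:200),
                        grid = seq(0, 1, by = 0.01))
  expect_lt(abs(roc2$auc - 0.5), 0.1)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(
    response = rep(c(1, 0), each = 200), predictor = c(esc, sil),
    direction = "<", quiet = TRUE))
  expect_equal(roc2$auc, as.numeric(ref), tolerance = 1e-8)

  # Monotone transform of the score leaves the AUC unchanged when the grid
  # covers the transformed values.
  fr3 <- sqrt(fr2)
  roc3 <- roc_calibrate(fr3, sprintf("e%03d", 1:200),
                        sprintf("s%03d", 1:200),
                        grid = sort(unique(c(0, fr3, 1))))
  roc2b <- roc_calibrate(fr2, sprintf("e%03d", 1:200),
                         sprintf("s%03d", 1:200),
                         grid = sort(unique(c(0, fr2, 1))))
  expect_equal(roc3$auc, roc2b$auc, tolerance = 1e-10)

  expect_error(roc_calibrate(fr, character(), c("s1")), "at least one")
  expect_error(roc_calibrate(fr, c("e1", "s1"), c("s1")), "disjoint")
})

test_that("escape fraction correlates with expression bias as constructed", {
  sm <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                       frac_escape = seq(0, 0.95, by = 0.05))
  de <- tibble::tibble(gene_id = sm$gene_id,
                       log2fc = 2 * sm$frac_escape + 1)
  r <- correlate_escape_with_bias(sm, de)
  expect_equal(r$pearson_r, 1.0)
  de$log2fc <- -de$log2fc
  expect_equal(correlate_escape_with_bias(sm, de)$pearson_r, -1.0)
  expect_error(correlate_escape_with_bias(sm[1:2, ], de), "fewer than 3")
})

test_that("classifier recovers escape truth on a separable cohort", {
  co <- simulate_cohort(cohort_spec(
    n_samples = 40, n_silent_genes = 60, n_escape_genes = 12,
    coverage_mean = 40, seed = 19))
  truth <- co$truth$genes
  silent_known <- truth$gene_id[!truth$escape][1:30]
  res <- classify_escape(co$sites, silent_known)
  joined <- dplyr::inner_join(res$summary, truth, by = "gene_id")
  sens <- mean(joined$population_call[joined$escape] == "escape")
  spec <- mean(joined$population_call[!joined$escape] == "silent")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.95)
  # The null's own genes are not re-scored by default.
  expect_false(any(res$calls$gene_id %in% silent_known))
  res2 <- classify_escape(co$sites, silent_known, rescore_silent = TRUE)
  expect_true(any(res2$calls$gene_id %in% silent_known))
})

test_that("false-escape rate on a null cohort stays near alpha", {
  co <- simulate_cohort(cohort_spec(
    n_samples = 50, n_silent_genes = 100, n_escape_genes = 0, seed = 5))
  silent_known <- co$truth$genes$gene_id[1:50]
  res <- classify_escape(co$sites, silent_known)
  expect_lt(abs(mean(res$calls$escape_flag) - 0.05), 0.02)
  expect_equal(sum(res$summary$population_call == "escape"), 0L)
})
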