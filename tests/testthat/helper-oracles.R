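# Independent oracles and small fixture builders used across tests.

# Brute-force per-basepair replication-timing oracle: walk every basepair of
# the gene, look up the segment covering it (0 when uncovered), average over
# the full gene length.
rt_bruteforce <- function(gene, segments) {
  bps <- seq(gene$start, gene$end)
  vals <- vapply(bps, function(b) {
    hit <- segments$chrom == gene$chrom &
      segments$start <= (b - 1) & (b - 1) < segments$end
    if (any(hit)) segments$value[which(hit)[1]] else 0
  }, numeric(1))
  if (all(vals == 0)) {
    seen <- vapply(bps, function(b) any(
      segments$chrom == gene$chrom &
        segments$start <= (b - 1) & (b - 1) < segments$end), logical(1))
    if (!any(seen)) return(NA_real_)
  }
  mean(vals)
}

# Exhaustive permutation-null oracle: enumerate every k-subset of the
# universe and compute the exact upper-tail probability of each TF's count.
perm_exact <- function(gene_list, reference, assignments, mode = "genes") {
  k <- length(gene_list)
  obs <- observed_counts(gene_list, assignments, mode = mode)
  tfs <- sort(unique(assignments$tf_name))
  obs <- obs[tfs]
  combos <- utils::combn(reference, k, simplify = FALSE)
  counts <- t(vapply(combos, function(g)
    observed_counts(g, assignments, mode = mode)[tfs], numeric(length(tfs))))
  if (length(tfs) == 1) counts <- matrix(counts, ncol = 1)
  p <- vapply(seq_along(tfs), function(j) mean(counts[, j] >= obs[j]),
              numeric(1))
  stats::setNames(p, tfs)
}

# Small annotation: n genes of width 1000 spaced 10 kb apart on one
# chromosome, TSS at the gene start.
toy_annotation <- function(n = 5, chrom = "chr1", spacing = 10000,
                           width = 1000) {
  start <- 1 + (seq_len(n) - 1) * spacing
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom, start = start, end = start + width - 1,
    tss = start, strand = "+",
    stratum = rep(c("S1", "S5"), length.out = n))
}

# Clonality-null rows built directly from known parameters.
toy_null <- function(sample_id = "S1", mu = 0.9, sigma = 0.05,
                     n_obs = 50L) {
  tibble::tibble(sample_id = sample_id, mu = mu, sigma = sigma,
                 n_obs = n_obs, usable = TRUE)
}
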