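# Per-gene replication timing, TAD entropy, and timing-vs-bias regressions.

#' Basepair-weighted replication timing per gene
#'
#' For each gene, `R_gene = sum_i(R_i * bpOverlap_i) / totalBpInGene`, where
#' the sum runs over replication-timing segments overlapping the gene,
#' `bpOverlap_i` is the overlapped length, and `totalBpInGene` is the full
#' gene length. By a literal reading of that formula, gene basepairs not
#' covered by any segment contribute zero to the numerator while the
#' denominator stays the full length (`uncovered = "zero"`);
#' `uncovered = "renormalize"` divides by the covered length instead. Genes
#' with no covered basepairs get `NA`. Overlapping segments within one track
#' violate the track's invariant and raise an error.
#'
#' @param genes Gene annotation tibble (1-based inclusive `start`, `end`).
#' @param segments Replication track tibble: `chrom`, `start`, `end`
#'   (0-based half-open), `value`.
#' @param uncovered `"zero"` (default) or `"renormalize"`.
#' @return Tibble with `gene_id`, `R_gene`, `covered_bp`, `gene_bp`.
#' @export
replication_timing_per_gene <- function(genes, segments,
                                        uncovered = c("zero",
                                                      "renormalize")) {
  uncovered <- match.arg(uncovered)
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  assert_columns(segments, c("chrom", "start", "end", "value"),
                 "replication track")
  if (any(genes$end < genes$start)) {
    stop("gene with non-positive length", call. = FALSE)
  }
  gr_seg <- bed_to_granges(segments)
  if (!all(GenomicRanges::isDisjoint(gr_seg))) {
    stop("replication track contains overlapping segments", call. = FALSE)
  }
  gr_gene <- genes_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_seg, ignore.strand = TRUE)
  ov <- IRanges::pintersect(gr_gene[S4Vectors::queryHits(hits)],
                            gr_seg[S4Vectors::subjectHits(hits)])
  contrib <- tibble::tibble(
    gi = S4Vectors::queryHits(hits),
    bp = GenomicRanges::width(ov),
    val = segments$value[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::group_by(.data$gi) |>
    dplyr::summarise(num = sum(.data$val * .data$bp),
                     covered = sum(.data$bp), .groups = "drop")
  gene_bp <- genes$end - genes$start + 1
  num <- covered <- rep(0, nrow(genes))
  num[contrib$gi] <- contrib$num
  covered[contrib$gi] <- contrib$covered
  denom <- if (uncovered == "zero") gene_bp else covered
  tibble::tibble(
    gene_id = genes$gene_id,
    R_gene = ifelse(covered > 0, num / denom, NA_real_),
    covered_bp = covered,
    gene_bp = gene_bp
  )
}

#' Single-term entropy of a sex-biased gene proportion
#'
#' `entropy(p) = -p * log(p)` with `entropy(0) = 0` by continuity. Under the
#' natural log (default) the maximum is `1/e` at `p = 1/e`. This is the
#' single-term expression, not the binary Shannon entropy;
#' `binary = TRUE` gives `-p*log(p) - (1-p)*log(1-p)` for users expecting
#' the standard definition.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param base Logarithm base (default `exp(1)`; the choice rescales values
#'   uniformly and does not affect rankings).
#' @param binary Use the two-term binary entropy instead.
#' @return Numeric vector of entropies (>= 0).
#' @export
tad_entropy_value <- function(p, base = exp(1), binary = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  term <- function(q) ifelse(q > 0, -q * log(q, base = base), 0)
  if (binary) term(p) + term(1 - p) else term(p)
}

#' TAD-level entropy of sex-biased gene content
#'
#' Assigns each gene to the TAD containing its TSS, computes per TAD the
#' proportion `p` of assigned genes that are sex-biased, and the entropy
#' `-p * log(p)` (low entropy at high `p` indicates sex-biased genes
#' clustering together). Records are emitted for every TAD; those
#' containing sex-biased genes are flagged. Genes whose TSS falls outside
#' every TAD are counted in the `n_unassigned` attribute.
#'
#' @param tads TAD tibble: `chrom`, `start`, `end` (0-based half-open),
#'   optional `tad_id`; TADs must be non-overlapping within a chromosome.
#' @param genes Gene annotation tibble with `gene_id`, `chrom`, `tss`.
#' @param sexbiased Character vector of sex-biased gene ids.
#' @param base,binary Passed to [tad_entropy_value()].
#' @return Tibble with `tad_id`, `chrom`, `start`, `end`, `n_genes`,
#'   `n_sexbiased`, `p`, `entropy`, `contains_sexbiased`; attribute
#'   `n_unassigned` counts genes outside all TADs.
#' @export
tad_entropy <- function(tads, genes, sexbiased, base = exp(1),
                        binary = FALSE) {
  assert_columns(tads, c("chrom", "start", "end"), "TAD table")
  assert_columns(genes, c("gene_id", "chrom", "tss"), "annotation")
  if (!"tad_id" %in% names(tads)) {
    tads$tad_id <- sprintf("TAD%04d", seq_len(nrow(tads)))
  }
  gr_tads <- bed_to_granges(tads)
  if (!all(GenomicRanges::isDisjoint(gr_tads))) {
    stop("TADs overlap within a chromosome", call. = FALSE)
  }
  gr_tss <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$tss, width = 1))
  hits <- GenomicRanges::findOverlaps(gr_tss, gr_tads, ignore.strand = TRUE)
  assigned <- tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    tad_id = tads$tad_id[S4Vectors::subjectHits(hits)]
  )
  n_unassigned <- nrow(genes) - dplyr::n_distinct(assigned$gene_id)
  per_tad <- assigned |>
    dplyr::group_by(.data$tad_id) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_sexbiased = sum(.data$gene_id %in% sexbiased),
                     .groups = "drop")
  out <- dplyr::left_join(tads, per_tad, by = "tad_id") |>
    dplyr::mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      n_sexbiased = dplyr::coalesce(.data$n_sexbiased, 0L),
      p = ifelse(.data$n_genes > 0,
                 .data$n_sexbiased / .data$n_genes, NA_real_),
      entropy = ifelse(is.na(.data$p), NA_real_,
                       tad_entropy_value(dplyr::coalesce(.data$p, 0),
                                         base = base, binary = binary)),
      contains_sexbiased = .data$n_sexbiased > 0
    ) |>
    dplyr::select("tad_id", "chrom", "start", "end", "n_genes",
                  "n_sexbiased", "p", "entropy", "contains_sexbiased")
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Regress per-gene replication timing on sex bias
#'
#' `mode = "continuous"` fits ordinary least squares of the per-gene
#' replication-timing value on the female-vs-male log2 fold change;
#' `mode = "categorical"` fits timing on the bias category (`female`,
#' `male`, `unbiased`) with `unbiased` as the reference level, and also
#' reports the F test of the categorical term (the ANOVA-style three-group
#' comparison).
#'
#' @param timing Tibble with `gene_id`, `R_gene` (from
#'   [replication_timing_per_gene()]).
#' @param de_table Tibble with `gene_id` and `log2fc` (continuous mode) or
#'   `bias` (categorical mode).
#' @param mode `"continuous"` or `"categorical"`.
#' @return A `regression_fit` (see [fit_univariate()]); for categorical
#'   mode the fit carries an `f_test` attribute with the group F statistic
#'   and p value.
#' @export
regress_timing_on_bias <- function(timing, de_table,
                                   mode = c("continuous", "categorical")) {
  mode <- match.arg(mode)
  assert_columns(timing, c("gene_id", "R_gene"), "timing table")
  if (mode == "continuous") {
    assert_columns(de_table, c("gene_id", "log2fc"), "DE table")
    df <- dplyr::inner_join(timing, de_table[, c("gene_id", "log2fc")],
                            by = "gene_id")
    df <- df[complete.cases(df[, c("R_gene", "log2fc")]), ]
    if (nrow(df) < 3) stop("fewer than 3 genes with both values",
                           call. = FALSE)
    fit_ols(R_gene ~ log2fc, df)
  } else {
    assert_columns(de_table, c("gene_id", "bias"), "DE table")
    df <- dplyr::inner_join(timing, de_table[, c("gene_id", "bias")],
                            by = "gene_id")
    df <- df[complete.cases(df[, c("R_gene", "bias")]), ]
    if (nrow(df) < 3) stop("fewer than 3 genes with both values",
                           call. = FALSE)
    df$bias <- factor(df$bias,
                      levels = intersect(c("unbiased", "female", "male"),
                                         unique(df$bias)))
    fit <- fit_ols(R_gene ~ bias, df)
    lmfit <- attr(fit, "lm")
    an <- anova(lmfit)
    attr(fit, "f_test") <- tibble::tibble(
      term = "bias", f = an[["F value"]][1], p = an[["Pr(>F)"]][1])
    fit
  }
}
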