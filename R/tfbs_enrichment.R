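# Gene-list permutation test for TF binding-site enrichment near TSSs.
#
# Binding sites are split into proximal (within a window, default 2 kb, of a
# gene's transcription start site) and distal (everything else). For a gene
# list of interest (e.g. female-biased sDEGs), the observed per-TF proximal
# binding is compared to a null built by repeatedly drawing random gene
# lists of the same size from a reference gene universe.

#' Assign TF binding sites to the proximal windows of gene TSSs
#'
#' A site is proximal to a gene when its interval overlaps
#' `[TSS - window, TSS + window]` on the genomic axis, regardless of strand.
#' A site may be proximal to several genes and is counted for each. Genes
#' without a TSS are skipped with a warning.
#'
#' @param tfbs Tibble of binding sites: `chrom`, `start`, `end` (0-based
#'   half-open), `tf_name`.
#' @param annotation Gene annotation tibble with `gene_id`, `chrom`, `tss`
#'   (1-based).
#' @param window Half-width of the proximal window in bp (> 0).
#' @return Tibble with one row per (gene, TF) pair having at least one
#'   proximal site: `gene_id`, `tf_name`, `n_sites`.
#' @export
assign_proximal <- function(tfbs, annotation, window = 2000) {
  assert_columns(tfbs, c("chrom", "start", "end", "tf_name"), "TFBS table")
  assert_columns(annotation, c("gene_id", "chrom", "tss"), "annotation")
  assert_scalar_number(window, "window", lower = 0, strict_lower = TRUE)
  if (any(is.na(annotation$tss))) {
    warning(sprintf("%d gene(s) without a TSS skipped",
                    sum(is.na(annotation$tss))))
    annotation <- annotation[!is.na(annotation$tss), ]
  }
  gr_win <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = pmax(1, annotation$tss - window),
                     end = annotation$tss + window))
  gr_tfbs <- bed_to_granges(tfbs)
  hits <- GenomicRanges::findOverlaps(gr_tfbs, gr_win, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(tibble::tibble(gene_id = character(), tf_name = character(),
                          n_sites = integer()))
  }
  tibble::tibble(
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    tf_name = tfbs$tf_name[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::count(.data$gene_id, .data$tf_name, name = "n_sites") |>
    dplyr::arrange(.data$gene_id, .data$tf_name)
}

# Reference-gene x TF count matrix underlying both the observed counts and
# the permutation null. In "genes" mode entries are 0/1 (gene has >= 1
# proximal site of the TF); in "sites" mode they are site counts.
proximal_matrix <- function(assignments, universe, mode) {
  tfs <- sort(unique(assignments$tf_name))
  m <- matrix(0, nrow = length(universe), ncol = length(tfs),
              dimnames = list(universe, tfs))
  a <- assignments[assignments$gene_id %in% universe, ]
  if (nrow(a) > 0) {
    idx <- cbind(match(a$gene_id, universe), match(a$tf_name, tfs))
    m[idx] <- if (mode == "genes") 1 else a$n_sites
  }
  m
}

#' Observed per-TF proximal binding counts for a gene list
#'
#' In the default `"genes"` mode the count for a TF is the number of listed
#' genes with at least one proximal site of that TF (robust to site
#' clustering); `"sites"` mode sums the proximal sites instead.
#'
#' @param gene_list Character vector of gene ids (non-empty).
#' @param assignments Proximal assignment tibble from [assign_proximal()].
#' @param mode `"genes"` (default) or `"sites"`.
#' @return Named numeric vector of per-TF counts (all TFs present in
#'   `assignments`, zero where unbound).
#' @export
observed_counts <- function(gene_list, assignments,
                            mode = c("genes", "sites")) {
  mode <- match.arg(mode)
  if (length(gene_list) == 0) stop("empty gene list", call. = FALSE)
  assert_columns(assignments, c("gene_id", "tf_name", "n_sites"),
                 "assignment table")
  m <- proximal_matrix(assignments, unique(gene_list), mode)
  colSums(m)
}

#' Permutation test for per-TF proximal binding enrichment
#'
#' Draws `n_perm` random gene lists of the same size as the input list,
#' uniformly without replacement from the reference universe, recomputes the
#' per-TF proximal binding count for each draw, and reports the empirical
#' upper-tail probability with the add-one correction
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, which is never zero.
#'
#' @param gene_list Character vector of genes of interest (must be contained
#'   in `reference_genes` and no larger).
#' @param reference_genes Character vector: the gene universe to permute
#'   over.
#' @param assignments Proximal assignment tibble from [assign_proximal()].
#' @param n_perm Number of permutations (>= 1; the default matches common
#'   practice of 1000 draws).
#' @param seed Optional integer seed for the permutation stream.
#' @param mode Count mode, as in [observed_counts()].
#' @return Tibble sorted by `p_perm`: `tf_name`, `observed`, `null_mean`,
#'   `null_sd`, `fold_change` (`observed / null_mean`, `NA` when the null
#'   mean is zero), `p_perm`, `p_adj` (Benjamini-Hochberg), `n_perm`.
#' @export
permutation_test <- function(gene_list, reference_genes, assignments,
                             n_perm = 1000, seed = NULL,
                             mode = c("genes", "sites")) {
  mode <- match.arg(mode)
  if (length(gene_list) == 0) stop("empty gene list", call. = FALSE)
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  gene_list <- unique(gene_list)
  reference_genes <- unique(reference_genes)
  if (length(gene_list) > length(reference_genes)) {
    stop("gene list is larger than the reference universe", call. = FALSE)
  }
  if (!all(gene_list %in% reference_genes)) {
    stop("the reference universe must contain every listed gene",
         call. = FALSE)
  }
  m <- proximal_matrix(assignments, reference_genes, mode)
  obs <- colSums(m[match(gene_list, reference_genes), , drop = FALSE])
  k <- length(gene_list)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null <- matrix(0, nrow = n_perm, ncol = ncol(m),
                 dimnames = list(NULL, colnames(m)))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(reference_genes), k)
    null[b, ] <- colSums(m[idx, , drop = FALSE])
  }
  null_mean <- unname(colMeans(null))
  null_sd <- unname(apply(null, 2, sd))
  obs <- unname(as.numeric(obs))
  p_perm <- unname(
    (1 + colSums(sweep(null, 2, obs, `>=`))) / (n_perm + 1))
  tibble::tibble(
    tf_name = colnames(m),
    observed = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    fold_change = ifelse(null_mean > 0, obs / null_mean, NA_real_),
    p_perm = p_perm,
    p_adj = p.adjust(p_perm, method = "BH"),
    n_perm = as.integer(n_perm)
  ) |>
    dplyr::arrange(.data$p_perm, .data$tf_name)
}

#' Select a sex-biased gene list from a differential-expression table
#'
#' Sex-biased differentially expressed genes (sDEGs) are genes with nominal
#' p strictly below the threshold; direction splits them by the sign of the
#' female-vs-male log2 fold change (positive = female-biased).
#'
#' @param de_table Tibble with gene ids, a p-value column and a log2
#'   fold-change column.
#' @param direction `"both"` (default), `"female"` (log2fc > 0) or
#'   `"male"` (log2fc < 0).
#' @param threshold Nominal p-value cutoff (strict `<`).
#' @param p_col,lfc_col,gene_col Column names.
#' @return Character vector of gene ids.
#' @export
select_sdeg_input <- function(de_table, direction = c("both", "female",
                                                      "male"),
                              threshold = 0.05, p_col = "p",
                              lfc_col = "log2fc", gene_col = "gene_id") {
  direction <- match.arg(direction)
  assert_columns(de_table, c(gene_col, p_col, lfc_col), "DE table")
  keep <- de_table[[p_col]] < threshold
  if (direction == "female") keep <- keep & de_table[[lfc_col]] > 0
  if (direction == "male") keep <- keep & de_table[[lfc_col]] < 0
  de_table[[gene_col]][!is.na(keep) & keep]
}
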