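# Quality filtering of allelic observations at heterozygous exonic sites.
#
# Input is tabular (per-read or per-site), not BAM: upstream variant calling
# is out of scope and a documented TSV schema replaces it.

#' Filter read-level (or site-level) observations on edit distance and
#' mapping quality
#'
#' Retains exactly the rows with `NM <= nm_max` and `MQ > mq_min`,
#' preserving input order. The default `mq_min = 175` reflects the summed
#' mapping-quality convention of the upstream caller rather than the
#' conventional 0-60 per-read scale; it is configurable. The operation is
#' idempotent.
#'
#' @param reads A tibble of observations; site-level tables with `mean_NM` /
#'   `mean_MQ` columns can be filtered by pointing `nm_col` / `mq_col` at
#'   them.
#' @param nm_max Maximum edit distance to the reference (kept when
#'   `NM <= nm_max`).
#' @param mq_min Mapping-quality threshold (kept when `MQ > mq_min`,
#'   strictly).
#' @param nm_col,mq_col Names of the NM and MQ columns.
#' @return The filtered tibble, same columns, original order.
#' @export
filter_reads <- function(reads, nm_max = 6, mq_min = 175,
                         nm_col = "NM", mq_col = "MQ") {
  assert_columns(reads, c(nm_col, mq_col), "read table")
  keep <- reads[[nm_col]] <= nm_max & reads[[mq_col]] > mq_min
  reads[!is.na(keep) & keep, ]
}

#' Pile up filtered reads into per-site allele counts
#'
#' Aggregates reads per (sample, chrom, pos), keeping only positions present
#' in the supplied genotypically heterozygous site list, and assigns each
#' site to the annotated gene(s) containing it. The major allele is the more
#' covered one; on a tie the lexicographically smaller base is recorded as
#' major (the ratio is 0.5 either way). A site falling in several
#' overlapping genes is emitted once per gene with `ambiguous = TRUE`
#' (with a warning), or dropped entirely under `overlap_mode = "strict"`.
#'
#' @param reads Tibble with `sample_id`, `chrom`, `pos` (1-based), `allele`.
#' @param het_sites Tibble with `sample_id`, `chrom`, `pos` listing
#'   genotypically heterozygous positions per sample.
#' @param annotation Gene annotation tibble (1-based inclusive `start`,
#'   `end`).
#' @param overlap_mode `"all"` (default: duplicate into every overlapping
#'   gene) or `"strict"` (assign to none).
#' @return Tibble of allelic sites: `sample_id`, `chrom`, `pos`, `gene_id`,
#'   `major_count`, `total_count`, `het_flag`, `ambiguous`.
#' @export
pileup_sites <- function(reads, het_sites, annotation,
                         overlap_mode = c("all", "strict")) {
  overlap_mode <- match.arg(overlap_mode)
  assert_columns(reads, c("sample_id", "chrom", "pos", "allele"),
                 "read table")
  assert_columns(het_sites, c("sample_id", "chrom", "pos"), "het site list")
  reads <- dplyr::semi_join(reads, het_sites,
                            by = c("sample_id", "chrom", "pos"))
  if (nrow(reads) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = numeric(), gene_id = character(),
                          major_count = integer(), total_count = integer(),
                          het_flag = logical(), ambiguous = logical()))
  }
  counts <- reads |>
    dplyr::count(.data$sample_id, .data$chrom, .data$pos, .data$allele,
                 name = "n") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos,
                   dplyr::desc(.data$n), .data$allele)
  sites <- counts |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::summarise(major_count = .data$n[1],
                     total_count = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(het_flag = TRUE)

  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos, width = 1))
  gr_genes <- genes_to_granges(annotation)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(sites[0, ] |> dplyr::mutate(
    gene_id = character(0), ambiguous = logical(0)))
  out <- sites[S4Vectors::queryHits(hits), ]
  out$gene_id <- annotation$gene_id[S4Vectors::subjectHits(hits)]
  n_genes_per_site <- table(S4Vectors::queryHits(hits))
  dup_sites <- as.integer(names(n_genes_per_site)[n_genes_per_site > 1])
  out$ambiguous <- S4Vectors::queryHits(hits) %in% dup_sites
  if (any(out$ambiguous)) {
    warning(sprintf(
      "%d site(s) overlap more than one gene%s",
      length(dup_sites),
      if (overlap_mode == "strict") "; dropped (strict mode)"
      else "; assigned to every overlapping gene"))
    if (overlap_mode == "strict") out <- out[!out$ambiguous, ]
  }
  dplyr::select(out, "sample_id", "chrom", "pos", "gene_id",
                "major_count", "total_count", "het_flag", "ambiguous")
}

#' Filter allelic sites on coverage and exclusion regions
#'
#' Drops sites with `total_count < min_cov` and sites falling in any of the
#' supplied exclusion interval sets (RNA-editing sites, non-uniquely-mappable
#' regions). Exclusion intervals are 0-based half-open; a 1-based site at
#' `pos` is excluded when `pos - 1` lies in `[start, end)`. Idempotent.
#'
#' @param sites Allelic-site tibble with `chrom`, `pos`, `total_count`.
#' @param exclusion_beds A list of exclusion interval sets, each either a
#'   tibble (`chrom`, `start`, `end`) or a path to a BED file; `NULL` or an
#'   empty list applies the coverage filter only.
#' @param min_cov Minimum total coverage (sites with `total_count < min_cov`
#'   are removed; the default keeps 20x and above).
#' @return The filtered tibble.
#' @export
filter_sites <- function(sites, exclusion_beds = NULL, min_cov = 20) {
  assert_columns(sites, c("chrom", "pos", "total_count"), "site table")
  sites <- sites[sites$total_count >= min_cov, ]
  if (is.null(exclusion_beds) || length(exclusion_beds) == 0 ||
      nrow(sites) == 0) {
    return(sites)
  }
  if (!is.list(exclusion_beds) || is.data.frame(exclusion_beds)) {
    exclusion_beds <- list(exclusion_beds)
  }
  excl <- dplyr::bind_rows(lapply(exclusion_beds, function(x) {
    if (is.character(x)) read_bed(x) else {
      assert_columns(x, c("chrom", "start", "end"), "exclusion set")
      x[, c("chrom", "start", "end")]
    }
  }))
  if (nrow(excl) == 0) return(sites)
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos, width = 1))
  hit <- IRanges::overlapsAny(gr_sites, bed_to_granges(excl),
                              ignore.strand = TRUE)
  sites[!hit, ]
}

#' Allelic ratio of a site
#'
#' The allelic ratio is the coverage of the major allele divided by the
#' total coverage at the site, hence always in `[0.5, 1]`: 0.5 indicates
#' balanced biallelic expression, 1 monoallelic expression.
#'
#' @param major_count Reads supporting the major allele (vectorised).
#' @param total_count Total reads at the site; must be > 0.
#' @return Numeric vector `major_count / total_count`.
#' @export
allelic_ratio <- function(major_count, total_count) {
  if (any(total_count <= 0)) {
    stop("allelic ratio is undefined at zero total coverage", call. = FALSE)
  }
  if (any(major_count > total_count) ||
      any(major_count < total_count - major_count)) {
    stop("'major_count' must satisfy total/2 <= major_count <= total",
         call. = FALSE)
  }
  major_count / total_count
}

#' Read an allelic-site TSV
#'
#' @param path Path to a tab-separated table with at least `sample_id`,
#'   `chrom`, `pos`, `gene_id`, `major_count`, `total_count`.
#' @return A tibble.
#' @export
read_allelic_sites <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("sample_id", "chrom", "pos", "gene_id",
                      "major_count", "total_count"),
                 sprintf("allelic site file '%s'", path))
  x
}
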