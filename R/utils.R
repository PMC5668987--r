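# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-facing seed fans out into
# independent streams (per sample, per stage) so that enlarging a simulation
# does not reshuffle draws already made for existing units. Kept below
# .Machine$integer.max so set.seed() always accepts it.
sub_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(stream) * 524287 +
                as.numeric(index)) %% 2147483629)
}

assert_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    stop(sprintf("'%s' must be a single number in %s%s, %s]",
                 name, if (strict_lower) "(" else "[",
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' Read a BED-like interval file
#'
#' Intervals are 0-based, half-open, as in the BED standard. Lines beginning
#' with `#` or `track` are skipped. A malformed line (too few fields, a
#' non-numeric or inverted interval) aborts with the offending line number.
#'
#' @param path Path to a tab-separated BED-like file.
#' @param extra What the fourth column holds: `"none"` (plain 3-column BED),
#'   `"name"` (feature name, e.g. a TF or TAD id), or `"value"` (a numeric
#'   signal, e.g. replication timing).
#' @param extra_name Column name to give the fourth column.
#' @return A tibble with columns `chrom`, `start`, `end` and, if requested,
#'   the named fourth column.
#' @export
read_bed <- function(path, extra = c("none", "name", "value"),
                     extra_name = "name") {
  extra <- match.arg(extra)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_want <- if (extra == "none") 3L else 4L
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < n_want) {
      stop(sprintf("malformed BED line %d in '%s': expected at least %d fields",
                   idx[k], path, n_want), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("malformed BED line %d in '%s': bad interval [%s, %s)",
                   idx[k], path, f[2], f[3]), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[`, character(1), 2L)),
    end   = as.numeric(vapply(fields, `[`, character(1), 3L))
  )
  if (extra == "name") out[[extra_name]] <- vapply(fields, `[`, character(1), 4L)
  if (extra == "value") {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1]]
      stop(sprintf("malformed BED line %d in '%s': non-numeric value column",
                   bad, path), call. = FALSE)
    }
    out[[extra_name]] <- v
  }
  out
}

#' Write intervals as BED
#'
#' @param df Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally further columns, written in order after the first three.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  assert_columns(df, c("chrom", "start", "end"), "BED table")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

# BED (0-based half-open) -> GRanges (1-based closed).
bed_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# Gene annotation (1-based inclusive start/end) -> GRanges.
genes_to_granges <- function(annotation) {
  assert_columns(annotation, c("gene_id", "chrom", "start", "end"),
                 "gene annotation")
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end)
  )
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  gr
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `start`, `end`
#' (1-based, inclusive), `tss`, `strand`, and optionally `stratum`
#' (e.g. PAR1, S1..S5, XAR/XCR labels).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble, one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(ann, c("gene_id", "chrom", "start", "end", "tss"),
                 sprintf("annotation file '%s'", path))
  ann
}

#' Read a gene-list file (one gene id per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of gene ids (blank lines and `#` comments
#'   dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
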