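# Clonality-aware classification of X-inactivation escape.
#
# Lymphoblastoid cell lines are oligo/monoclonal, so the same X tends to be
# inactive in most cells of a sample and silenced genes show allelic ratios
# skewed toward 1 by an individual-specific amount. The classifier absorbs
# that nuisance with a per-individual null: the mean and standard deviation
# of allelic ratios over a curated list of known silent genes estimate the
# sample's clonality, and every other gene is tested against the normal
# distribution they define. A gene whose aggregated ratio sits significantly
# below the null escapes inactivation in that individual; population-wide,
# a gene escaping in more than a cutoff fraction (default 30%) of
# informative individuals is called an escape gene.

#' Estimate the per-individual clonality null
#'
#' For each sample, pools the per-site allelic ratios of the known silent
#' genes and records their mean and standard deviation. The standard
#' deviation is floored at `sigma_min` so that monoclonal, high-coverage
#' samples (with essentially zero spread) do not produce degenerate
#' z-scores. Samples with fewer than `min_null_obs` silent-gene observations
#' are marked unusable and produce no downstream calls.
#'
#' @param sites Filtered allelic-site tibble (`sample_id`, `gene_id`,
#'   `major_count`, `total_count`).
#' @param silent_genes Character vector of known silent gene ids.
#' @param min_null_obs Minimum silent-gene observations per sample.
#' @param sigma_min Lower floor on the null standard deviation.
#' @param level `"site"` (default: pool per-site ratios, maximising the
#'   number of observations) or `"gene"` (one unweighted mean ratio per
#'   silent gene, then mean/SD over genes).
#' @return Tibble with one row per sample: `sample_id`, `mu`, `sigma`,
#'   `n_obs`, `usable`.
#' @export
fit_clonality_null <- function(sites, silent_genes, min_null_obs = 10,
                               sigma_min = 0.01,
                               level = c("site", "gene")) {
  level <- match.arg(level)
  assert_columns(sites, c("sample_id", "gene_id", "major_count",
                          "total_count"), "site table")
  if (length(silent_genes) == 0) {
    stop("'silent_genes' must contain at least one gene id", call. = FALSE)
  }
  s <- sites[sites$gene_id %in% silent_genes, ]
  s$ratio <- allelic_ratio(s$major_count, s$total_count)
  if (level == "gene") {
    s <- s |>
      dplyr::group_by(.data$sample_id, .data$gene_id) |>
      dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  }
  null <- s |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mu = mean(.data$ratio),
                     sigma = sd(.data$ratio),
                     n_obs = dplyr::n(), .groups = "drop")
  # Samples absent from the silent-gene subset get an unusable row.
  all_samples <- unique(sites$sample_id)
  missing <- setdiff(all_samples, null$sample_id)
  if (length(missing) > 0) {
    null <- dplyr::bind_rows(null, tibble::tibble(
      sample_id = missing, mu = NA_real_, sigma = NA_real_, n_obs = 0L))
  }
  null |>
    dplyr::mutate(
      sigma = pmax(dplyr::coalesce(.data$sigma, 0), sigma_min),
      usable = .data$n_obs >= min_null_obs,
      mu = ifelse(.data$usable, .data$mu, NA_real_),
      sigma = ifelse(.data$usable, .data$sigma, NA_real_)
    ) |>
    dplyr::arrange(.data$sample_id)
}

#' Test genes against the clonality null, per sample
#'
#' Aggregates each gene's sites into one allelic ratio per (gene, sample) —
#' by default a coverage-weighted mean of site ratios — and standardises it
#' against that sample's null: `z = (ratio - mu) / sigma`. The default test
#' asks whether the gene's ratio is significantly different from the silent
#' null (two-sided); a gene escapes in that individual when `p < alpha`.
#' Escape pulls ratios toward 0.5, below the silenced null on the `[0.5, 1]`
#' scale, so a one-sided lower-tail variant is available via
#' `sided = "lower"`.
#'
#' Because the null's mean and standard deviation are estimated from a
#' finite number of silent-gene observations, the default reference
#' distribution is the Student-t predictive distribution for a new
#' observation (`z` rescaled by `sqrt(1 + 1/n_obs)`, `n_obs - 1` degrees of
#' freedom), which keeps the per-call false-escape rate at its nominal
#' level; `null_dist = "normal"` uses the plain normal instead.
#'
#' Samples with an unusable null yield no call (which is distinct from a
#' silent call). Known silent genes define the null and are excluded from
#' the output unless `rescore_silent = TRUE`.
#'
#' @param sites Filtered allelic-site tibble.
#' @param null Clonality-null tibble from [fit_clonality_null()].
#' @param alpha Per-individual significance level.
#' @param weighting `"coverage"` (default) or `"unweighted"` gene-level
#'   aggregation of site ratios.
#' @param sided `"two"` (default) or `"lower"`.
#' @param null_dist `"t"` (default: predictive t accounting for estimated
#'   null parameters) or `"normal"` (plain normal tail probability).
#' @param silent_genes Gene ids to exclude from re-classification (usually
#'   the null's silent list).
#' @param rescore_silent Re-score the silent genes for diagnostics.
#' @return Tibble of per-(sample, gene) calls: `sample_id`, `gene_id`,
#'   `ratio`, `n_sites`, `z`, `p`, `escape_flag`.
#' @export
test_gene_sample <- function(sites, null, alpha = 0.05,
                             weighting = c("coverage", "unweighted"),
                             sided = c("two", "lower"),
                             null_dist = c("t", "normal"),
                             silent_genes = character(),
                             rescore_silent = FALSE) {
  weighting <- match.arg(weighting)
  sided <- match.arg(sided)
  null_dist <- match.arg(null_dist)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_columns(sites, c("sample_id", "gene_id", "major_count",
                          "total_count"), "site table")
  if (!rescore_silent && length(silent_genes) > 0) {
    sites <- sites[!sites$gene_id %in% silent_genes, ]
  }
  sites$ratio <- allelic_ratio(sites$major_count, sites$total_count)
  w <- if (weighting == "coverage") sites$total_count else rep(1, nrow(sites))
  sites$w <- w
  calls <- sites |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::summarise(
      ratio = sum(.data$ratio * .data$w) / sum(.data$w),
      n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(
      null[null$usable, c("sample_id", "mu", "sigma", "n_obs")],
      by = "sample_id") |>
    dplyr::mutate(
      z = (.data$ratio - .data$mu) / .data$sigma,
      zs = if (null_dist == "t") {
        .data$z / sqrt(1 + 1 / .data$n_obs)
      } else {
        .data$z
      },
      p = {
        tail_p <- if (null_dist == "t") {
          stats::pt(if (sided == "lower") .data$zs else -abs(.data$zs),
                    df = .data$n_obs - 1)
        } else {
          pnorm(if (sided == "lower") .data$zs else -abs(.data$zs))
        }
        if (sided == "lower") tail_p else 2 * tail_p
      },
      escape_flag = .data$p < alpha
    ) |>
    dplyr::select("sample_id", "gene_id", "ratio", "n_sites", "z", "p",
                  "escape_flag")
  calls
}

#' Aggregate per-sample escape calls to population-level gene summaries
#'
#' A gene is called an escape gene when it escapes in strictly more than
#' `cutoff` of its informative samples (samples with a usable call), and is
#' only classified at all when at least `min_informative` samples are
#' informative; otherwise the population call is `"insufficient_data"`.
#'
#' @param calls Per-(sample, gene) call tibble from [test_gene_sample()].
#' @param cutoff Population escape-fraction cutoff (strict `>`); the default
#'   0.30 maximises sensitivity plus specificity against curated gene lists
#'   (see [roc_calibrate()]).
#' @param min_informative Minimum informative samples per gene.
#' @param annotation Optional annotation carrying a `stratum` column to copy
#'   onto the summary.
#' @return Tibble with one row per gene: `gene_id`, `n_informative`,
#'   `frac_escape`, `population_call`, and `stratum` when available.
#' @export
aggregate_population <- function(calls, cutoff = 0.30, min_informative = 5,
                                 annotation = NULL) {
  assert_columns(calls, c("sample_id", "gene_id", "escape_flag"),
                 "call table")
  out <- calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_informative = dplyr::n(),
      frac_escape = mean(.data$escape_flag), .groups = "drop") |>
    dplyr::mutate(population_call = dplyr::case_when(
      .data$n_informative < min_informative ~ "insufficient_data",
      .data$frac_escape > cutoff ~ "escape",
      TRUE ~ "silent"
    ))
  if (!is.null(annotation) && "stratum" %in% names(annotation)) {
    out <- dplyr::left_join(
      out, annotation[, c("gene_id", "stratum")], by = "gene_id")
  }
  out
}

#' Classify escape genes end-to-end
#'
#' Convenience wrapper: fits the per-individual clonality null from the
#' silent list, tests every other gene in every sample, and aggregates to
#' population-level calls.
#'
#' @inheritParams fit_clonality_null
#' @inheritParams test_gene_sample
#' @inheritParams aggregate_population
#' @return A list with `null`, `calls`, and `summary` tibbles.
#' @export
classify_escape <- function(sites, silent_genes, alpha = 0.05,
                            cutoff = 0.30, min_informative = 5,
                            min_null_obs = 10, sigma_min = 0.01,
                            weighting = "coverage", sided = "two",
                            null_dist = "t", rescore_silent = FALSE,
                            annotation = NULL) {
  null <- fit_clonality_null(sites, silent_genes,
                             min_null_obs = min_null_obs,
                             sigma_min = sigma_min)
  calls <- test_gene_sample(sites, null, alpha = alpha,
                            weighting = weighting, sided = sided,
                            null_dist = null_dist,
                            silent_genes = silent_genes,
                            rescore_silent = rescore_silent)
  summary <- aggregate_population(calls, cutoff = cutoff,
                                  min_informative = min_informative,
                                  annotation = annotation)
  list(null = null, calls = calls, summary = summary)
}

#' Calibrate the population escape-fraction cutoff by ROC
#'
#' Sweeps a grid of cutoffs on the population escape fraction and scores
#' each against curated known-escape and known-silent gene lists. The
#' positive class is the known silent gene (a true positive is a silent gene
#' correctly kept silent, i.e. `frac_escape <= cutoff`); the symmetric
#' escape-oriented sensitivity/specificity are the same two numbers swapped,
#' and the AUC is identical under either orientation. The AUC is computed by
#' the trapezoidal rule over (1 - specificity, sensitivity), and the chosen
#' cutoff maximises Youden's J = sensitivity + specificity - 1 (ties broken
#' toward the smallest cutoff).
#'
#' @param frac_escape Named numeric vector of per-gene population escape
#'   fractions (names are gene ids), or a summary tibble from
#'   [aggregate_population()].
#' @param known_escape,known_silent Disjoint character vectors of curated
#'   gene ids; each must have at least one gene with an escape fraction.
#' @param grid Cutoff grid on `[0, 1]`.
#' @return A list of class `roc_curve`: `curve` (tibble with `cutoff`,
#'   `sensitivity`, `specificity`, `youden`), `auc`, `chosen_cutoff`,
#'   `misclassification` (of known escape genes at the chosen cutoff).
#' @export
roc_calibrate <- function(frac_escape, known_escape, known_silent,
                          grid = seq(0, 1, by = 0.01)) {
  if (is.data.frame(frac_escape)) {
    assert_columns(frac_escape, c("gene_id", "frac_escape"),
                   "summary table")
    frac_escape <- setNames(frac_escape$frac_escape, frac_escape$gene_id)
  }
  if (length(intersect(known_escape, known_silent)) > 0) {
    stop("known escape and known silent lists must be disjoint",
         call. = FALSE)
  }
  esc <- frac_escape[names(frac_escape) %in% known_escape]
  sil <- frac_escape[names(frac_escape) %in% known_silent]
  if (length(esc) == 0 || length(sil) == 0) {
    stop(paste("calibration requires at least one known escape and one",
               "known silent gene with an escape fraction"), call. = FALSE)
  }
  grid <- sort(unique(grid))
  sens <- vapply(grid, function(c) mean(sil <= c), numeric(1))
  spec <- vapply(grid, function(c) mean(esc > c), numeric(1))
  curve <- tibble::tibble(cutoff = grid, sensitivity = sens,
                          specificity = spec,
                          youden = sens + spec - 1)
  # Trapezoid over ROC points, anchored at (0,0) and (1,1).
  x <- c(0, sort(1 - spec), 1)
  y <- c(0, sort(sens), 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  best <- which(curve$youden == max(curve$youden))[1]
  chosen <- curve$cutoff[best]
  structure(list(
    curve = curve,
    auc = auc,
    chosen_cutoff = chosen,
    misclassification = mean(esc <= chosen)
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC calibration: AUC = %.3f, chosen cutoff = %.2f (Youden), %d cutoffs\n",
    x$auc, x$chosen_cutoff, nrow(x$curve)))
  cat(sprintf("known-escape misclassification at chosen cutoff: %.1f%%\n",
              100 * x$misclassification))
  invisible(x)
}

#' Correlate population escape fraction with sex-biased expression
#'
#' Computes the Pearson correlation (with two-sided p) between the per-gene
#' population escape fraction and the female-vs-male log2 fold change over
#' the genes shared by both tables; the Spearman rank correlation is
#' reported alongside.
#'
#' @param summaries Summary tibble with `gene_id`, `frac_escape`.
#' @param de_table Differential-expression tibble with `gene_id`, `log2fc`.
#' @return One-row tibble: `n`, `pearson_r`, `pearson_p`, `spearman_rho`.
#' @export
correlate_escape_with_bias <- function(summaries, de_table) {
  assert_columns(summaries, c("gene_id", "frac_escape"), "summary table")
  assert_columns(de_table, c("gene_id", "log2fc"), "DE table")
  shared <- dplyr::inner_join(
    summaries[, c("gene_id", "frac_escape")],
    de_table[, c("gene_id", "log2fc")], by = "gene_id")
  shared <- shared[complete.cases(shared), ]
  if (nrow(shared) < 3) {
    stop("fewer than 3 genes shared between escape summaries and DE table",
         call. = FALSE)
  }
  ct <- cor.test(shared$frac_escape, shared$log2fc, method = "pearson")
  rho <- suppressWarnings(
    cor.test(shared$frac_escape, shared$log2fc, method = "spearman"))
  tibble::tibble(n = nrow(shared),
                 pearson_r = unname(ct$estimate),
                 pearson_p = ct$p.value,
                 spearman_rho = unname(rho$estimate))
}
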