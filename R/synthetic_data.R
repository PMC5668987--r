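# Synthetic cohorts, genomes and covariate tables with known truth.
#
# The generator stands in for the real inputs (LCL RNA-seq allelic counts,
# ENCODE regulatory tracks, per-gene evolutionary covariates) and reproduces
# the statistical structure the downstream stages assume: individual-specific
# clonal skew of silent-gene allelic ratios, near-balanced escape-gene
# ratios, binomial count noise at a given coverage, TF binding tracks
# enriched near a designated gene set, piecewise-smooth replication signals,
# tiling TADs, and covariate tables with a planted regression structure.

#' Specify a synthetic allelic-expression cohort
#'
#' The clonal skew of each simulated individual is drawn as
#' `theta = 0.5 + 0.5 * Beta(clonality_alpha, clonality_beta)`, so that skews
#' lie in `[0.5, 1)`; silenced genes then show major-haplotype read counts
#' `Binomial(coverage, theta)` while escape genes show
#' `Binomial(coverage, escape_ratio_mean)` with a ratio near 0.5. Defaults
#' give a mean skew of 0.85 (alpha = 7, beta = 3), one informative
#' heterozygous site per gene per individual, and 50x mean coverage —
#' a sparse, LCL-like regime.
#'
#' @param n_samples Number of individuals (>= 1).
#' @param n_silent_genes,n_escape_genes Numbers of silenced and escaping
#'   genes.
#' @param sites_per_gene Informative heterozygous sites per gene per sample
#'   (fixed count).
#' @param coverage_mean Mean read coverage per site.
#' @param clonality_alpha,clonality_beta Beta shape parameters of the clonal
#'   skew distribution; both must be > 0.
#' @param escape_ratio_mean Expected allele fraction of the designated
#'   haplotype at escape genes, in `[0.5, 1)`; 0.5 means fully biallelic.
#' @param escape_penetrance Probability that an escape gene actually escapes
#'   in a given individual (1 = escapes in everyone; lower values model
#'   inter-individual variability in escape).
#' @param fail_nm_frac,fail_mq_frac Fractions of sites given failing
#'   edit-distance (NM > 6) or mapping-quality (MQ <= 175) summaries, to
#'   exercise the quality filters.
#' @param coverage_model `"poisson"` (default) or `"nbinom"` (negative
#'   binomial with size `coverage_size`, for overdispersed coverage).
#' @param coverage_size Negative-binomial size parameter when
#'   `coverage_model = "nbinom"`.
#' @param seed Integer seed; identical seeds reproduce identical cohorts
#'   byte-for-byte, and per-sample sub-streams mean adding samples does not
#'   reshuffle existing ones.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 50L, n_silent_genes = 100L,
                        n_escape_genes = 20L, sites_per_gene = 1L,
                        coverage_mean = 50, clonality_alpha = 7,
                        clonality_beta = 3, escape_ratio_mean = 0.5,
                        escape_penetrance = 1, fail_nm_frac = 0,
                        fail_mq_frac = 0,
                        coverage_model = c("poisson", "nbinom"),
                        coverage_size = 10, seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(n_silent_genes, "n_silent_genes", lower = 0)
  assert_scalar_number(n_escape_genes, "n_escape_genes", lower = 0)
  assert_scalar_number(sites_per_gene, "sites_per_gene", lower = 1)
  assert_scalar_number(coverage_mean, "coverage_mean", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(clonality_alpha, "clonality_alpha", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(clonality_beta, "clonality_beta", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(escape_ratio_mean, "escape_ratio_mean",
                       lower = 0.5, upper = 1 - 1e-12)
  assert_scalar_number(escape_penetrance, "escape_penetrance",
                       lower = 0, upper = 1)
  assert_scalar_number(fail_nm_frac, "fail_nm_frac", lower = 0, upper = 1)
  assert_scalar_number(fail_mq_frac, "fail_mq_frac", lower = 0, upper = 1)
  assert_scalar_number(coverage_size, "coverage_size", lower = 0,
                       strict_lower = TRUE)
  structure(list(
    n_samples = as.integer(n_samples),
    n_silent_genes = as.integer(n_silent_genes),
    n_escape_genes = as.integer(n_escape_genes),
    sites_per_gene = as.integer(sites_per_gene),
    coverage_mean = coverage_mean,
    clonality_alpha = clonality_alpha,
    clonality_beta = clonality_beta,
    escape_ratio_mean = escape_ratio_mean,
    escape_penetrance = escape_penetrance,
    fail_nm_frac = fail_nm_frac,
    fail_mq_frac = fail_mq_frac,
    coverage_model = coverage_model,
    coverage_size = coverage_size,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Minimal single-chromosome annotation used when the caller supplies none:
# evenly spaced genes along an X-sized chromosome.
default_x_annotation <- function(n_genes, chrom = "chrX",
                                 chrom_length = 155e6, gene_length = 2e4) {
  spacing <- floor((chrom_length - gene_length) / max(n_genes, 1))
  start <- 1 + (seq_len(n_genes) - 1) * spacing
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = chrom,
    start = start,
    end = start + gene_length - 1,
    tss = start,
    strand = "+",
    stratum = rep(c("S1", "S2", "S3", "S4", "S5"), length.out = n_genes)
  )
}

#' Simulate a cohort of per-site allelic observations
#'
#' For each individual a clonal skew `theta` is drawn once; silenced genes
#' produce haplotype counts `Binomial(coverage, theta)` and escape genes
#' `Binomial(coverage, escape_ratio_mean)`. The emitted table carries both
#' the raw simulated haplotype count (`hap_count`, whose expected fraction is
#' exactly the simulated allele probability) and the derived
#' `major_count = max(hap_count, coverage - hap_count)` that downstream
#' allelic-ratio analysis consumes.
#'
#' @param spec A [cohort_spec()].
#' @param annotation Optional gene annotation tibble (`gene_id`, `chrom`,
#'   `start`, `end`, `tss`); a default X-chromosome layout is generated when
#'   omitted. Must contain at least `n_silent_genes + n_escape_genes` genes.
#' @return A list with elements:
#'   \describe{
#'     \item{sites}{tibble of per-site observations: `sample_id`, `chrom`,
#'       `pos` (1-based), `gene_id`, `hap_count`, `major_count`,
#'       `total_count`, `mean_NM`, `mean_MQ`.}
#'     \item{truth}{list of `samples` (per-sample `theta`), `genes`
#'       (per-gene `escape` flag), and the `annotation` used.}
#'   }
#' @export
simulate_cohort <- function(spec, annotation = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_genes <- spec$n_silent_genes + spec$n_escape_genes
  if (is.null(annotation)) annotation <- default_x_annotation(n_genes)
  assert_columns(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  if (nrow(annotation) < n_genes) {
    stop(sprintf("annotation provides %d genes but the spec requires %d",
                 nrow(annotation), n_genes), call. = FALSE)
  }
  ann <- annotation[seq_len(n_genes), ]

  # Which genes escape is decided once, in its own stream.
  set.seed(sub_seed(spec$seed, 0L, stream = 1L))
  escape_flag <- rep(FALSE, n_genes)
  if (spec$n_escape_genes > 0) {
    escape_flag[sample.int(n_genes, spec$n_escape_genes)] <- TRUE
  }
  gene_truth <- tibble::tibble(gene_id = ann$gene_id, escape = escape_flag)

  draw_cov <- function(n) {
    cov <- if (spec$coverage_model == "poisson") {
      rpois(n, spec$coverage_mean)
    } else {
      rnbinom(n, size = spec$coverage_size, mu = spec$coverage_mean)
    }
    cov
  }

  per_sample <- vector("list", spec$n_samples)
  theta <- numeric(spec$n_samples)
  sample_ids <- sprintf("S%04d", seq_len(spec$n_samples))
  gene_rep <- rep(seq_len(n_genes), each = spec$sites_per_gene)
  for (i in seq_len(spec$n_samples)) {
    set.seed(sub_seed(spec$seed, i, stream = 2L))
    th <- 0.5 + 0.5 * rbeta(1, spec$clonality_alpha, spec$clonality_beta)
    theta[i] <- th
    n_site <- length(gene_rep)
    pos <- ann$start[gene_rep] +
      floor(runif(n_site) * (ann$end[gene_rep] - ann$start[gene_rep] + 1))
    cov <- draw_cov(n_site)
    escapes_here <- escape_flag[gene_rep] &
      (runif(n_site) < spec$escape_penetrance)
    p <- ifelse(escapes_here, spec$escape_ratio_mean, th)
    hap <- rbinom(n_site, cov, p)
    nm <- rbinom(n_site, 6, 0.25)
    mq <- runif(n_site, 180, 255)
    fail_nm <- runif(n_site) < spec$fail_nm_frac
    nm[fail_nm] <- 7L + rpois(sum(fail_nm), 1)
    fail_mq <- runif(n_site) < spec$fail_mq_frac
    mq[fail_mq] <- runif(sum(fail_mq), 0, 175)
    keep <- cov > 0
    per_sample[[i]] <- tibble::tibble(
      sample_id = sample_ids[i],
      chrom = ann$chrom[gene_rep],
      pos = pos,
      gene_id = ann$gene_id[gene_rep],
      hap_count = hap,
      major_count = pmax(hap, cov - hap),
      total_count = cov,
      mean_NM = as.numeric(nm),
      mean_MQ = mq
    )[keep, ]
  }
  list(
    sites = dplyr::bind_rows(per_sample),
    truth = list(
      samples = tibble::tibble(sample_id = sample_ids, theta = theta),
      genes = gene_truth,
      annotation = ann
    )
  )
}

#' Specify a synthetic genome with regulatory tracks
#'
#' @param n_genes Total number of genes, allocated to chromosomes in
#'   proportion to length.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param gene_length Gene length in bp (constant).
#' @param n_tfs Number of transcription factors.
#' @param enriched_tf_ids Character vector of TF names (e.g. `"TF01"`)
#'   planted preferentially near the target gene set.
#' @param n_sites_per_tf Background binding sites per TF, placed uniformly.
#' @param planted_rate For each enriched TF and each target gene, the
#'   probability of planting an extra binding site inside the proximal
#'   window of that gene's TSS.
#' @param proximal_window Half-width (bp) of the proximal window around the
#'   TSS used for planting.
#' @param tfbs_width Width (bp) of each binding site.
#' @param tad_size_mean Mean TAD size in bp; TADs tile each chromosome
#'   without overlap. With `tad_size_cv = 0` the tiling is regular, so
#'   `tad_size_mean` equal to the chromosome length yields exactly one TAD.
#' @param tad_size_cv Coefficient of variation of TAD sizes (0 = regular
#'   tiling).
#' @param replication_tile Tile size (bp) of the piecewise-constant
#'   replication-timing track.
#' @param replication_smoothness Width (tiles) of the moving average applied
#'   to the raw signal; larger = smoother.
#' @param replication_amplitude Signal range; values are rescaled to
#'   `[0, amplitude]` (larger = earlier replication).
#' @param seed Integer seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 200L,
                        chrom_lengths = c(chr1 = 60e6, chr2 = 40e6),
                        gene_length = 2e4, n_tfs = 10L,
                        enriched_tf_ids = character(),
                        n_sites_per_tf = 400L, planted_rate = 0.5,
                        proximal_window = 2000L, tfbs_width = 15L,
                        tad_size_mean = 1e6, tad_size_cv = 0,
                        replication_tile = 5e4,
                        replication_smoothness = 20L,
                        replication_amplitude = 1, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("'chrom_lengths' must be a named vector", call. = FALSE)
  }
  assert_scalar_number(tad_size_mean, "tad_size_mean", lower = 1)
  assert_scalar_number(planted_rate, "planted_rate", lower = 0, upper = 1)
  if (proximal_window * 2 > min(chrom_lengths)) {
    stop("'proximal_window' is larger than the smallest chromosome",
         call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), chrom_lengths = chrom_lengths,
    gene_length = gene_length, n_tfs = as.integer(n_tfs),
    enriched_tf_ids = enriched_tf_ids,
    n_sites_per_tf = as.integer(n_sites_per_tf),
    planted_rate = planted_rate,
    proximal_window = as.integer(proximal_window),
    tfbs_width = as.integer(tfbs_width),
    tad_size_mean = tad_size_mean, tad_size_cv = tad_size_cv,
    replication_tile = replication_tile,
    replication_smoothness = as.integer(replication_smoothness),
    replication_amplitude = replication_amplitude,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Simulate a genome annotation with TFBS, replication-timing and TAD tracks
#'
#' Enriched TFs receive extra binding sites inside the proximal window of
#' target-gene TSSs at rate `planted_rate`; all other binding is uniform.
#' The replication signal is a smoothed random walk, piecewise constant on
#' tiles; TADs tile each chromosome without gaps or overlap.
#'
#' @param spec A [genome_spec()].
#' @param target_gene_set Character vector of gene ids (subset of the
#'   generated genes) near which enriched TFs are planted. May be a set of
#'   indices into the generated gene table (resolved by position) or gene
#'   ids of the form `"G0001"`; required when `enriched_tf_ids` is
#'   non-empty.
#' @return A list: `annotation` (tibble, 1-based intervals with `tss`,
#'   `strand`), `tfbs` (tibble, 0-based half-open, `tf_name`),
#'   `replication` (tibble with `value`), `tads` (tibble with `tad_id`),
#'   and `truth` (per-TF `enriched` flag plus the target set).
#' @export
simulate_genome <- function(spec, target_gene_set = character()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(sub_seed(spec$seed, 0L, stream = 3L))
  chroms <- names(spec$chrom_lengths)
  lens <- as.numeric(spec$chrom_lengths)

  # Genes allocated proportionally to chromosome length.
  n_per <- floor(spec$n_genes * lens / sum(lens))
  rem <- spec$n_genes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
  ann <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    n <- n_per[ci]
    if (n == 0) return(NULL)
    max_start <- lens[ci] - spec$gene_length
    start <- sort(1 + floor(runif(n) * max_start))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    end <- start + spec$gene_length - 1
    tibble::tibble(
      chrom = chroms[ci], start = start, end = end,
      tss = ifelse(strand == "+", start, end), strand = strand
    )
  }))
  ann$gene_id <- sprintf("G%04d", seq_len(nrow(ann)))
  ann <- ann[, c("gene_id", "chrom", "start", "end", "tss", "strand")]

  tf_names <- sprintf("TF%02d", seq_len(spec$n_tfs))
  if (length(spec$enriched_tf_ids) > 0 &&
      !all(spec$enriched_tf_ids %in% tf_names)) {
    stop("'enriched_tf_ids' must name generated TFs (TF01, TF02, ...)",
         call. = FALSE)
  }
  if (is.numeric(target_gene_set)) {
    target_gene_set <- ann$gene_id[target_gene_set]
  }
  if (length(spec$enriched_tf_ids) > 0 && length(target_gene_set) == 0) {
    stop("enriched TFs requested but 'target_gene_set' is empty",
         call. = FALSE)
  }
  if (!all(target_gene_set %in% ann$gene_id)) {
    stop("'target_gene_set' must be a subset of the generated genes",
         call. = FALSE)
  }

  # Background TFBS uniform over the genome; planted sites for enriched TFs
  # inside the proximal window of each target gene at rate planted_rate.
  chrom_prob <- lens / sum(lens)
  w <- spec$tfbs_width
  targets <- ann[ann$gene_id %in% target_gene_set, ]
  tfbs <- dplyr::bind_rows(lapply(tf_names, function(tf) {
    ci <- sample.int(length(chroms), spec$n_sites_per_tf, replace = TRUE,
                     prob = chrom_prob)
    start <- floor(runif(spec$n_sites_per_tf) * (lens[ci] - w))
    out <- tibble::tibble(chrom = chroms[ci], start = start,
                          end = start + w, tf_name = tf)
    if (tf %in% spec$enriched_tf_ids && nrow(targets) > 0) {
      hit <- runif(nrow(targets)) < spec$planted_rate
      if (any(hit)) {
        tg <- targets[hit, ]
        lo <- pmax(0, tg$tss - spec$proximal_window)
        hi <- pmin(lens[match(tg$chrom, chroms)] - w,
                   tg$tss + spec$proximal_window - w)
        ps <- floor(lo + runif(nrow(tg)) * pmax(hi - lo, 1))
        out <- dplyr::bind_rows(out, tibble::tibble(
          chrom = tg$chrom, start = ps, end = ps + w, tf_name = tf
        ))
      }
    }
    out
  }))

  # Replication timing: smoothed white noise on fixed tiles, rescaled to
  # [0, amplitude]; piecewise constant, non-overlapping by construction.
  replication <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    n_tile <- max(1L, ceiling(lens[ci] / spec$replication_tile))
    raw <- rnorm(n_tile)
    k <- min(spec$replication_smoothness, n_tile)
    sm <- as.numeric(stats::filter(raw, rep(1 / k, k), sides = 2,
                                   circular = TRUE))
    rng <- range(sm)
    val <- if (diff(rng) > 0) {
      (sm - rng[1]) / diff(rng) * spec$replication_amplitude
    } else {
      rep(spec$replication_amplitude / 2, n_tile)
    }
    start <- (seq_len(n_tile) - 1) * spec$replication_tile
    tibble::tibble(chrom = chroms[ci], start = start,
                   end = pmin(start + spec$replication_tile, lens[ci]),
                   value = round(val, 6))
  }))

  # TADs tile each chromosome exactly.
  tads <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    bounds <- 0
    repeat {
      last <- bounds[length(bounds)]
      if (last >= lens[ci]) break
      size <- if (spec$tad_size_cv > 0) {
        max(1, round(rnorm(1, spec$tad_size_mean,
                           spec$tad_size_cv * spec$tad_size_mean)))
      } else {
        spec$tad_size_mean
      }
      bounds <- c(bounds, min(last + size, lens[ci]))
    }
    tibble::tibble(chrom = chroms[ci], start = bounds[-length(bounds)],
                   end = bounds[-1])
  }))
  tads$tad_id <- sprintf("TAD%04d", seq_len(nrow(tads)))

  list(
    annotation = ann,
    tfbs = tfbs,
    replication = replication,
    tads = tads,
    truth = list(
      tfs = tibble::tibble(tf_name = tf_names,
                           enriched = tf_names %in% spec$enriched_tf_ids),
      target_genes = target_gene_set
    )
  )
}

#' Default planted coefficients for the covariate simulator
#'
#' Names follow the model terms of [fit_dnds_model()] and
#' [fit_breadth_model()]: dN/dS responds to X-region (XCR vs XAR), XY-pair
#' status, average expression, escape status and disease status; expression
#' breadth responds to sex-bias category, dN/dS and average expression.
#'
#' @return A list with numeric vectors `dnds` and `breadth`.
#' @export
covariate_coefficients <- function() {
  list(
    dnds = c(intercept = 0.20, region_XCR = -0.03, xy_pair = 0.04,
             avg_expr = -0.005, escape = 0.05, disease = 0.01),
    breadth = c(intercept = 30, bias_female = -2.3, bias_male = -1.2,
                dnds = -10, avg_expr = 0.5)
  )
}

#' Simulate a per-gene evolutionary covariate table
#'
#' Generates dN/dS, expression breadth (clamped to the 1-56 tissue range),
#' mean expression, XY-pair / X-region / disease flags and a sex-bias label
#' so that the stated linear models hold with Gaussian noise of the given
#' standard deviation. With `noise_sd = 0` the regression stages recover the
#' planted coefficients exactly; `integer_breadth = TRUE` additionally
#' rounds breadth to whole tissue counts (realistic, but then recovery is
#' only approximate).
#'
#' @param genes A tibble with `gene_id` and optionally `escape` (logical)
#'   and `bias` (`"female"`, `"male"`, `"unbiased"`); missing columns are
#'   generated.
#' @param coefficients A list as returned by [covariate_coefficients()].
#' @param noise_sd Residual standard deviation(s): a single number, or a
#'   named vector with elements `dnds` and `breadth`. Must be >= 0.
#' @param integer_breadth Round breadth to integers (default `FALSE`).
#' @param seed Integer seed.
#' @return A tibble with one row per gene: `gene_id`, `dnds`, `xy_pair`,
#'   `region`, `avg_expr`, `escape_status`, `disease_flag`, `breadth`,
#'   `bias`.
#' @export
simulate_covariates <- function(genes, coefficients = covariate_coefficients(),
                                noise_sd = 0.02, integer_breadth = FALSE,
                                seed = 1L) {
  assert_columns(genes, "gene_id", "genes")
  if (any(noise_sd < 0)) stop("'noise_sd' must be >= 0", call. = FALSE)
  sd_dnds <- if (!is.null(names(noise_sd))) noise_sd[["dnds"]] else noise_sd
  sd_breadth <- if (!is.null(names(noise_sd))) noise_sd[["breadth"]] else noise_sd
  b <- coefficients
  need <- c("intercept", "region_XCR", "xy_pair", "avg_expr", "escape",
            "disease")
  if (!all(need %in% names(b$dnds))) {
    stop("coefficients$dnds must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need_b <- c("intercept", "bias_female", "bias_male", "dnds", "avg_expr")
  if (!all(need_b %in% names(b$breadth))) {
    stop("coefficients$breadth must name: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(genes)
  set.seed(sub_seed(seed, 0L, stream = 4L))
  escape <- if ("escape" %in% names(genes)) genes$escape else runif(n) < 0.15
  bias <- if ("bias" %in% names(genes)) {
    genes$bias
  } else {
    sample(c("unbiased", "female", "male"), n, replace = TRUE,
           prob = c(0.8, 0.1, 0.1))
  }
  region <- sample(c("XAR", "XCR"), n, replace = TRUE)
  xy_pair <- runif(n) < 0.1
  disease <- runif(n) < 0.2
  avg_expr <- round(rlnorm(n, meanlog = 1, sdlog = 0.5), 4)

  dnds <- b$dnds[["intercept"]] +
    b$dnds[["region_XCR"]] * (region == "XCR") +
    b$dnds[["xy_pair"]] * xy_pair +
    b$dnds[["avg_expr"]] * avg_expr +
    b$dnds[["escape"]] * escape +
    b$dnds[["disease"]] * disease +
    rnorm(n, 0, sd_dnds)
  dnds <- pmax(dnds, 0)

  breadth <- b$breadth[["intercept"]] +
    b$breadth[["bias_female"]] * (bias == "female") +
    b$breadth[["bias_male"]] * (bias == "male") +
    b$breadth[["dnds"]] * dnds +
    b$breadth[["avg_expr"]] * avg_expr +
    rnorm(n, 0, sd_breadth)
  breadth <- pmin(pmax(breadth, 1), 56)
  if (integer_breadth) breadth <- round(breadth)

  tibble::tibble(
    gene_id = genes$gene_id,
    dnds = dnds,
    xy_pair = xy_pair,
    region = region,
    avg_expr = avg_expr,
    escape_status = ifelse(escape, "escape", "non-escape"),
    disease_flag = disease,
    breadth = breadth,
    bias = bias
  )
}

#' Simulate a differential-expression table consistent with escape truth
#'
#' Escaping genes receive positive (female-biased) log2 fold changes with
#' magnitude proportional to their population escape fraction when supplied;
#' silenced and autosomal genes get near-zero fold changes. P values are
#' generated from the planted effect so that genes with a real effect have
#' small nominal p.
#'
#' @param genes Tibble with `gene_id` and optionally `escape` (logical) or
#'   `frac_escape` (numeric in `[0,1]`).
#' @param effect_size Log2 fold change per unit escape fraction (or for an
#'   escaping gene when only the flag is available).
#' @param noise_sd Standard deviation of fold-change noise.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `log2fc` (female vs male), `p`, `fdr`.
#' @export
simulate_de_table <- function(genes, effect_size = 1.5, noise_sd = 0.1,
                              seed = 1L) {
  assert_columns(genes, "gene_id", "genes")
  set.seed(sub_seed(seed, 0L, stream = 5L))
  n <- nrow(genes)
  base <- if ("frac_escape" %in% names(genes)) {
    genes$frac_escape
  } else if ("escape" %in% names(genes)) {
    as.numeric(genes$escape)
  } else {
    rep(0, n)
  }
  log2fc <- effect_size * base + rnorm(n, 0, noise_sd)
  z <- log2fc / noise_sd
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(gene_id = genes$gene_id, log2fc = log2fc, p = p,
                 fdr = p.adjust(p, method = "BH"))
}
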