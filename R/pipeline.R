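# End-to-end orchestration: simulate -> filter -> escape -> enrich ->
# features -> regress, driven by a single configuration (R list or YAML
# file) with one seed fanned out into per-stage sub-streams.

#' Default pipeline configuration
#'
#' Returns the full configuration for a one-command synthetic demonstration
#' run: every stage enabled, inputs generated by the simulator, parameters
#' at their documented defaults.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed; every stage derives its own sub-stream
#'   from it.
#' @return A named list (a `RunConfig`).
#' @export
default_config <- function(outdir = tempfile("xciescape_run_"), seed = 7L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, filter = TRUE, escape = TRUE,
                  enrich = TRUE, features = TRUE, regress = TRUE),
    inputs = list(sites = NULL, annotation = NULL, tfbs = NULL,
                  replication = NULL, tads = NULL, de_table = NULL,
                  covariates = NULL, silent_genes = NULL,
                  escape_genes = NULL, exclusions = NULL),
    params = list(alpha = 0.05, cutoff = 0.30, min_informative = 5,
                  min_null_obs = 10, sigma_min = 0.01, min_cov = 20,
                  nm_max = 6, mq_min = 175, window = 2000, n_perm = 1000),
    simulate = list(
      cohort = list(n_samples = 50, n_silent_genes = 100,
                    n_escape_genes = 20, coverage_mean = 50),
      genome = list(n_genes = 200, n_tfs = 10,
                    enriched_tf_ids = "TF01", n_targets = 40)
    )
  )
}

#' Validate a pipeline configuration
#'
#' Schema and range checks plus stage-dependency checks (e.g. the escape
#' stage needs allelic sites from either the simulator or an input path).
#' Always returns a report rather than erroring; [run_pipeline()] refuses to
#' start when the report contains error rows.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure.
#' @return A tibble report with columns `level` (`"ok"`, `"note"`,
#'   `"error"`), `field`, `message`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  p <- config$params
  rows <- list()
  add <- function(level, field, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      level = level, field = field, message = message)
  }
  chk_range <- function(val, field, lo, hi, lo_open = FALSE,
                        hi_open = FALSE) {
    ok <- is.numeric(val) && length(val) == 1 && !is.na(val) &&
      (if (lo_open) val > lo else val >= lo) &&
      (if (hi_open) val < hi else val <= hi)
    if (ok) add("ok", field, sprintf("%s = %s", field, format(val)))
    else add("error", field,
             sprintf("%s = %s outside %s%s, %s%s", field, format(val),
                     if (lo_open) "(" else "[", format(lo), format(hi),
                     if (hi_open) ")" else "]"))
  }
  chk_range(p$alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  chk_range(p$cutoff, "cutoff", 0, 1)
  chk_range(p$min_informative, "min_informative", 1, Inf)
  chk_range(p$min_cov, "min_cov", 0, Inf)
  chk_range(p$nm_max, "nm_max", 0, Inf)
  chk_range(p$window, "window", 1, Inf)
  chk_range(p$n_perm, "n_perm", 1, Inf)
  if (is.numeric(p$mq_min) && p$mq_min > 60) {
    add("note", "mq_min", sprintf(
      "mq_min = %s exceeds the conventional 0-60 mapping-quality range (a summed-quality convention); kept as configured",
      format(p$mq_min)))
  }
  # Stage dependencies: every enabled downstream stage needs its input,
  # either from the simulator or from a supplied path.
  sim_on <- isTRUE(config$stages$simulate)
  need <- list(
    filter = "sites", escape = "sites", enrich = "tfbs",
    features = "replication", regress = "covariates")
  for (stage in names(need)) {
    if (!isTRUE(config$stages[[stage]])) next
    input <- need[[stage]]
    path <- config$inputs[[input]]
    if (sim_on) {
      add("ok", stage, sprintf("'%s' input provided by the simulator",
                               input))
    } else if (is.null(path)) {
      add("error", stage, sprintf(
        "stage '%s' enabled but input '%s' is neither simulated nor supplied",
        stage, input))
    } else if (!file.exists(path)) {
      add("error", stage, sprintf("input file '%s' does not exist", path))
    } else {
      add("ok", stage, sprintf("'%s' input: %s", input, path))
    }
  }
  dplyr::bind_rows(rows)
}

write_stage_output <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_tsv(df, path)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order simulate, filter, escape, enrich,
#' features, regress, writing plain TSV outputs plus a manifest recording
#' parameters, seeds, per-stage output paths and their checksums. A failed
#' stage halts the run; the manifest (written even then) records the failure
#' point. Two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config Configuration list or YAML path; see [default_config()].
#' @return The manifest tibble (`stage`, `status`, `output`, `md5`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  report <- validate_config(config)
  if (any(report$level == "error")) {
    stop("invalid configuration:\n  ",
         paste(report$message[report$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  seed <- config$seed
  manifest <- list()
  note <- function(stage, status, paths) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = status,
      output = if (length(paths)) basename(paths) else NA_character_,
      md5 = if (length(paths)) unname(tools::md5sum(paths)) else
        NA_character_)
  }
  finish <- function() {
    mf <- dplyr::bind_rows(manifest)
    readr::write_tsv(mf, file.path(outdir, "manifest.tsv"))
    mf
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    if (!isTRUE(config$stages[[stage]])) {
      note(stage, "skipped", character())
      return(invisible(NULL))
    }
    paths <- tryCatch(fun(), error = function(e) e)
    if (inherits(paths, "error")) {
      note(stage, paste0("failed: ", conditionMessage(paths)), character())
      finish()
      stop(sprintf("stage '%s' failed: %s", stage,
                   conditionMessage(paths)), call. = FALSE)
    }
    note(stage, "done", paths)
  }

  run_stage("simulate", function() {
    sc <- config$simulate$cohort
    sc$seed <- sub_seed(seed, 1L)
    cohort <- simulate_cohort(do.call(cohort_spec, sc))
    gs <- config$simulate$genome
    n_targets <- gs$n_targets %||% 40
    gs$n_targets <- NULL
    gs$seed <- sub_seed(seed, 2L)
    gspec <- do.call(genome_spec, gs)
    genome <- simulate_genome(gspec, target_gene_set = seq_len(n_targets))
    # Sex-biased DE structure: planted on the TFBS target genes genome-wide,
    # and on the escaping genes for the X cohort.
    de_genome <- simulate_de_table(
      dplyr::mutate(genome$annotation,
                    escape = .data$gene_id %in% genome$truth$target_genes),
      seed = sub_seed(seed, 3L))
    de_x <- simulate_de_table(cohort$truth$genes, seed = sub_seed(seed, 4L))
    covariates <- simulate_covariates(
      cohort$truth$genes, noise_sd = c(dnds = 0.02, breadth = 1),
      seed = sub_seed(seed, 5L))
    # Curated-style known lists: half of the truth, the rest held out.
    truth <- cohort$truth$genes
    silent_known <- truth$gene_id[!truth$escape]
    silent_known <- silent_known[seq_len(floor(length(silent_known) / 2))]
    escape_known <- truth$gene_id[truth$escape]
    escape_known <- escape_known[seq_len(max(1,
                                             floor(length(escape_known) / 2)))]
    state$cohort <- cohort; state$genome <- genome
    state$de_genome <- de_genome; state$de_x <- de_x
    state$covariates <- covariates
    state$silent_known <- silent_known; state$escape_known <- escape_known
    state$silent_eval <- setdiff(truth$gene_id[!truth$escape], silent_known)
    paths <- c(
      write_stage_output(cohort$sites, outdir, "sites.tsv"),
      write_stage_output(cohort$truth$annotation, outdir,
                         "annotation_x.tsv"),
      write_stage_output(cohort$truth$samples, outdir, "truth_samples.tsv"),
      write_stage_output(cohort$truth$genes, outdir, "truth_genes.tsv"),
      write_stage_output(genome$annotation, outdir, "annotation_genome.tsv"),
      write_bed(genome$tfbs, file.path(outdir, "tfbs.bed")),
      write_bed(genome$replication, file.path(outdir, "replication.bed")),
      write_bed(genome$tads, file.path(outdir, "tads.bed")),
      write_stage_output(genome$truth$tfs, outdir, "truth_tfs.tsv"),
      write_stage_output(de_genome, outdir, "de_genome.tsv"),
      write_stage_output(de_x, outdir, "de_x.tsv"),
      write_stage_output(covariates, outdir, "covariates.tsv"))
    writeLines(state$silent_known, file.path(outdir, "silent_genes.txt"))
    writeLines(state$escape_known, file.path(outdir, "escape_genes.txt"))
    c(paths, file.path(outdir, c("silent_genes.txt", "escape_genes.txt")))
  })

  run_stage("filter", function() {
    sites <- state$cohort$sites %||% read_allelic_sites(config$inputs$sites)
    filtered <- filter_reads(sites, nm_max = p$nm_max, mq_min = p$mq_min,
                             nm_col = "mean_NM", mq_col = "mean_MQ")
    filtered <- filter_sites(filtered,
                             exclusion_beds = config$inputs$exclusions,
                             min_cov = p$min_cov)
    state$filtered <- filtered
    write_stage_output(filtered, outdir, "filtered_sites.tsv")
  })

  run_stage("escape", function() {
    sites <- state$filtered %||% state$cohort$sites %||%
      read_allelic_sites(config$inputs$sites)
    silent <- state$silent_known %||%
      read_gene_list(config$inputs$silent_genes)
    ann <- if (!is.null(state$cohort)) state$cohort$truth$annotation else
      if (!is.null(config$inputs$annotation))
        read_annotation(config$inputs$annotation) else NULL
    res <- classify_escape(sites, silent, alpha = p$alpha,
                           cutoff = p$cutoff,
                           min_informative = p$min_informative,
                           min_null_obs = p$min_null_obs,
                           sigma_min = p$sigma_min, annotation = ann)
    state$escape <- res
    paths <- c(
      write_stage_output(res$null, outdir, "clonality_null.tsv"),
      write_stage_output(res$calls, outdir, "escape_calls.tsv"),
      write_stage_output(res$summary, outdir, "escape_summary.tsv"))
    esc_known <- state$escape_known %||%
      (if (!is.null(config$inputs$escape_genes))
        read_gene_list(config$inputs$escape_genes) else NULL)
    if (!is.null(esc_known)) {
      # Genes in the null's silent list are excluded from re-classification,
      # so the ROC is calibrated on held-out silent genes (scored by the
      # classifier) vs the known escape list.
      held_out_silent <- state$silent_eval %||%
        setdiff(res$summary$gene_id, esc_known)
      roc <- roc_calibrate(res$summary, known_escape = esc_known,
                           known_silent = held_out_silent)
      paths <- c(paths, write_stage_output(roc$curve, outdir,
                                           "roc_curve.tsv"))
    }
    de_x <- state$de_x
    if (!is.null(de_x)) {
      paths <- c(paths, write_stage_output(
        correlate_escape_with_bias(res$summary, de_x), outdir,
        "escape_bias_correlation.tsv"))
    }
    paths
  })

  run_stage("enrich", function() {
    tfbs <- if (!is.null(state$genome)) state$genome$tfbs else
      read_bed(config$inputs$tfbs, extra = "name", extra_name = "tf_name")
    ann <- if (!is.null(state$genome)) state$genome$annotation else
      read_annotation(config$inputs$annotation)
    de <- state$de_genome %||%
      readr::read_tsv(config$inputs$de_table, show_col_types = FALSE)
    assignments <- assign_proximal(tfbs, ann, window = p$window)
    sdegs <- select_sdeg_input(de, direction = "both")
    enr <- permutation_test(sdegs, ann$gene_id, assignments,
                            n_perm = p$n_perm,
                            seed = sub_seed(seed, 6L))
    state$enrichment <- enr
    write_stage_output(enr, outdir, "tfbs_enrichment.tsv")
  })

  run_stage("features", function() {
    g <- state$genome
    repl <- if (!is.null(g)) g$replication else
      read_bed(config$inputs$replication, extra = "value",
               extra_name = "value")
    tads <- if (!is.null(g)) g$tads else
      read_bed(config$inputs$tads, extra = "name", extra_name = "tad_id")
    ann <- if (!is.null(g)) g$annotation else
      read_annotation(config$inputs$annotation)
    de <- state$de_genome %||%
      readr::read_tsv(config$inputs$de_table, show_col_types = FALSE)
    timing <- replication_timing_per_gene(ann, repl)
    sdegs <- select_sdeg_input(de, direction = "both")
    entropy <- tad_entropy(tads, ann, sdegs)
    reg <- regress_timing_on_bias(timing, de, mode = "continuous")
    state$timing <- timing
    c(write_stage_output(timing, outdir, "replication_per_gene.tsv"),
      write_stage_output(entropy, outdir, "tad_entropy.tsv"),
      write_stage_output(tibble::as_tibble(reg), outdir,
                         "timing_regression.tsv"))
  })

  run_stage("regress", function() {
    cov <- state$covariates %||%
      readr::read_tsv(config$inputs$covariates, show_col_types = FALSE)
    fits <- list(
      dnds_model = fit_dnds_model(cov),
      breadth_model = fit_breadth_model(cov),
      dnds_on_escape = fit_univariate(cov, "dnds", "escape_status"))
    vapply(names(fits), function(nm) {
      write_stage_output(tibble::as_tibble(fits[[nm]]), outdir,
                         paste0(nm, ".tsv"))
    }, character(1))
  })

  mf <- finish()
  invisible(mf)
}
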