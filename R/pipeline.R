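#' End-to-end study orchestration
#'
#' [run_all()] executes simulate -> dose-response -> enrichment ->
#' benchmark from one configuration, writing every intermediate artifact
#' (TSV/CSV/GMT/JSON) plus a machine-readable manifest with file hashes,
#' seeds and package version, so a rerun with the same configuration is
#' byte-reproducible.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' All defaults mirror the study-scale parameter set (signature size 30,
#' 1000-gene variance prefilter, elastic-net mixing 0.5, 10x10-fold CV,
#' 10 external repeats); cohort and GSEA sizes default to a desk-scale
#' smoke configuration and are meant to be overridden.
#'
#' @param ... Overrides for any top-level field.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    discovery = list(n_samples = 60L, n_tissues = 6L, n_genes = 300L,
                     n_signal_genes = 10L, signal_effect = 0.5,
                     survival_noise_sd = 0.05,
                     dose_grid = c(1, 2, 3, 4, 6, 8), seed = 11L),
    validation = list(n_samples = 40L, n_tissues = 4L, n_genes = 300L,
                      n_signal_genes = 10L, signal_effect = 0.5,
                      survival_noise_sd = 0.05,
                      dose_grid = c(2, 4, 6), seed = 12L),
    shared_gene_fraction = 1.0,
    dose_range = c(0, 8),
    gene_sets = list(n_sets = 60L, n_planted = 3L,
                     size_range = c(10L, 40L), seed = 13L),
    gsea = list(n_perm = 200L, min_size = 5L, max_size = 500L,
                fdr_threshold = 0.05, seed = 14L),
    predictors = list(signature_size = 30L, n_keep = 1000L, K = 10L,
                      alpha_mix = 0.5, gamma_range = c(-6, 5),
                      n_lambda = 100L, inner_folds = 10L),
    evaluation = list(n_folds = 5L, n_iterations = 2L, n_repeats = 2L,
                      seed = 15L),
    models = c("single_gene", "rank_ensemble", "rank_multivariate",
               "mrmr_exhaustive", "mrmr_bootstrap", "elastic_net")
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, override)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- c("discovery", "validation", "shared_gene_fraction", "dose_range",
            "gene_sets", "gsea", "predictors", "evaluation", "models")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop("run_config missing field(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(is.list(cfg$discovery), is.list(cfg$validation),
            is.numeric(cfg$dose_range), length(cfg$dose_range) == 2L,
            is.numeric(cfg$shared_gene_fraction))
  known <- c("single_gene", "rank_ensemble", "rank_multivariate",
             "mrmr_exhaustive", "mrmr_bootstrap", "elastic_net")
  bad <- setdiff(cfg$models, known)
  if (length(bad) > 0L) {
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Fields absent from the file keep their [default_run_config()] values;
#' unknown fields are an error (fail fast, before any computation).
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(default_run_config, raw)
}

cohort_config_from <- function(lst) {
  do.call(cohort_config, lst)
}

#' Run the full pipeline
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and the benchmark result.
#' @export
run_all <- function(config, out_dir) {
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))
  artifacts <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }

  log_stage("stage simulate: discovery %d samples, validation %d samples",
            config$discovery$n_samples, config$validation$n_samples)
  pair <- generate_paired_cohorts(
    cohort_config_from(config$discovery),
    cohort_config_from(config$validation),
    shared_gene_fraction = config$shared_gene_fraction
  )
  emit(write_expression, pair$discovery$expr, "discovery_expression.tsv")
  emit(write_expression, pair$validation$expr, "validation_expression.tsv")
  emit(write_curves, pair$discovery$curves, "discovery_curves.csv")
  emit(write_curves, pair$validation$curves, "validation_curves.csv")
  emit(write_ground_truth, pair$discovery$truth, "discovery_truth.json")
  emit(write_ground_truth, pair$validation$truth, "validation_truth.json")
  gs_cfg <- config$gene_sets
  collection <- generate_gene_sets(
    universe = rownames(pair$discovery$expr),
    signal_genes = pair$discovery$truth$signal_gene_ids,
    n_sets = gs_cfg$n_sets, n_planted = gs_cfg$n_planted,
    size_range = gs_cfg$size_range, seed = gs_cfg$seed,
    signal_effects = pair$discovery$truth$effects
  )
  emit(write_gmt, collection, "gene_sets.gmt")

  log_stage("stage dose-response: fitting LQ model, dose range [%g, %g] Gy",
            config$dose_range[[1]], config$dose_range[[2]])
  prof_d <- compute_profiles(pair$discovery$curves, config$dose_range)
  prof_v <- compute_profiles(pair$validation$curves, config$dose_range)
  emit(write_profiles, prof_d, "discovery_profiles.csv")
  emit(write_profiles, prof_v, "validation_profiles.csv")
  log_stage("stage dose-response: %d/%d discovery and %d/%d validation lines profiled",
            nrow(prof_d), config$discovery$n_samples,
            nrow(prof_v), config$validation$n_samples)

  log_stage("stage gsea: %d sets, %d permutations",
            length(collection$sets), config$gsea$n_perm)
  y_d <- stats::setNames(prof_d$sf2, prof_d$sample_id)
  ranking <- rank_genes(pair$discovery$expr[, prof_d$sample_id], y_d)
  enr <- gsea(ranking, collection, n_perm = config$gsea$n_perm,
              min_size = config$gsea$min_size,
              max_size = config$gsea$max_size,
              seed = config$gsea$seed)
  emit(function(obj, path) data.table::fwrite(obj, path), enr,
       "enrichment.csv")
  log_stage("stage gsea: %d set(s) significant at FDR < %g",
            sum(enr$fdr_q < config$gsea$fdr_threshold),
            config$gsea$fdr_threshold)

  log_stage("stage benchmark: %d model(s), %dx%d-fold CV, %d repeats",
            length(config$models), config$evaluation$n_iterations,
            config$evaluation$n_folds, config$evaluation$n_repeats)
  p <- config$predictors
  specs <- stats::setNames(lapply(config$models, function(nm) {
    model_spec(name = nm, signature_size = p$signature_size,
               n_keep = p$n_keep, K = p$K, alpha_mix = p$alpha_mix,
               gamma_range = p$gamma_range, n_lambda = p$n_lambda,
               inner_folds = p$inner_folds)
  }), config$models)
  y_v <- stats::setNames(prof_v$sf2, prof_v$sample_id)
  bench <- run_benchmark(
    pair$discovery$expr[, prof_d$sample_id], y_d,
    pair$validation$expr[, prof_v$sample_id], y_v,
    specs = specs,
    n_folds = config$evaluation$n_folds,
    n_iterations = config$evaluation$n_iterations,
    n_repeats = config$evaluation$n_repeats,
    seed = config$evaluation$seed
  )
  emit(function(obj, path) data.table::fwrite(obj, path), bench$table,
       "benchmark.csv")
  emit(function(obj, path) {
    jsonlite::write_json(
      list(table = bench$table,
           per_iteration = lapply(bench$reports, `[[`, "per_iteration"),
           provenance = bench$provenance),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, bench, "benchmark.json")

  manifest <- list(
    config = unclass(config),
    seeds = list(discovery = config$discovery$seed,
                 validation = config$validation$seed,
                 gene_sets = config$gene_sets$seed,
                 gsea = config$gsea$seed,
                 evaluation = config$evaluation$seed),
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(artifacts))), basename(artifacts)),
    package_version = as.character(utils::packageVersion("radbench")),
    n_common_genes = length(intersect(rownames(pair$discovery$expr),
                                      rownames(pair$validation$expr)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("pipeline complete: %d artifacts in %s",
            length(artifacts) + 1L, out_dir)
  invisible(list(manifest = manifest, benchmark = bench))
}
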