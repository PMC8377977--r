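#' Synthetic radiogenomic cohorts with known ground truth
#'
#' The generator emulates a cell-line radiation screen: a log2-scale
#' expression matrix with tissue-of-origin block structure, a latent
#' radioresistance score that is a linear combination of standardized
#' signal-gene expression, per-line linear-quadratic parameters derived from
#' that score and calibrated so the true SF2 distribution matches a target
#' mean and standard deviation, and noisy clonogenic surviving fractions on
#' a configurable dose grid. Every stage of the downstream pipeline can be
#' tested against the planted truth.
#'
#' @name synthetic_data
NULL

#' Configuration for one synthetic cohort
#'
#' Defaults mirror the discovery screen this package is calibrated to:
#' 511 cell lines across 23 tissue types scored on the
#' \{1, 2, 3, 4, 6, 8\} Gy grid, with an SF2 distribution of mean 0.6 and
#' standard deviation 0.2.
#'
#' @param n_samples Number of cell lines.
#' @param n_tissues Number of tissue-of-origin blocks.
#' @param n_genes Number of genes in the cohort's universe.
#' @param n_signal_genes Number of genes carrying true association with
#'   radiosensitivity.
#' @param signal_effect Per-gene contribution of a standardized signal-gene
#'   expression value to the latent radioresistance score. 0 means no signal.
#' @param expression_noise_sd Standard deviation of i.i.d. Gaussian noise on
#'   expression (log2-like scale).
#' @param survival_noise_sd Standard deviation of multiplicative log-normal
#'   noise on observed surviving fractions.
#' @param tissue_effect_sd Standard deviation of additive per-tissue,
#'   per-gene mean shifts on expression.
#' @param dose_grid Doses (Gy, all > 0) at which survival is observed.
#' @param sf2_target_mean,sf2_target_sd Target mean (in (0,1)) and standard
#'   deviation (> 0) of the true SF2 distribution.
#' @param beta_alpha_ratio Ratio \eqn{\beta/\alpha}; the default 0.1
#'   corresponds to the radiobiologically typical \eqn{\alpha/\beta} = 10 Gy.
#'   Set to 0 for a pure exponential survival model.
#' @param tissue_couples_sf2 If `FALSE` (default) the latent
#'   radioresistance score is computed from the tissue-free component of
#'   signal-gene expression, so tissue blocks shape expression but not SF2;
#'   if `TRUE` the observed (tissue-shifted) expression feeds the latent
#'   score, confounding tissue with radiosensitivity.
#' @param seed Integer seed; all outputs are deterministic given the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 511L,
                          n_tissues = 23L,
                          n_genes = 2000L,
                          n_signal_genes = 30L,
                          signal_effect = 0.5,
                          expression_noise_sd = 1,
                          survival_noise_sd = 0.05,
                          tissue_effect_sd = 0.5,
                          dose_grid = c(1, 2, 3, 4, 6, 8),
                          sf2_target_mean = 0.6,
                          sf2_target_sd = 0.2,
                          beta_alpha_ratio = 0.1,
                          tissue_couples_sf2 = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_tissues = as.integer(n_tissues),
    n_genes = as.integer(n_genes), n_signal_genes = as.integer(n_signal_genes),
    signal_effect = signal_effect,
    expression_noise_sd = expression_noise_sd,
    survival_noise_sd = survival_noise_sd,
    tissue_effect_sd = tissue_effect_sd,
    dose_grid = as.numeric(dose_grid),
    sf2_target_mean = sf2_target_mean, sf2_target_sd = sf2_target_sd,
    beta_alpha_ratio = beta_alpha_ratio,
    tissue_couples_sf2 = isTRUE(tissue_couples_sf2),
    seed = as.integer(seed)
  )
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2")
  if (cfg$n_signal_genes > cfg$n_genes) stop("n_signal_genes must be <= n_genes")
  if (length(cfg$dose_grid) == 0L) stop("dose_grid must be non-empty")
  if (any(cfg$dose_grid <= 0)) stop("all doses must be > 0")
  if (!(cfg$sf2_target_mean > 0 && cfg$sf2_target_mean < 1)) {
    stop("sf2_target_mean must lie in (0, 1)")
  }
  if (cfg$sf2_target_sd <= 0) stop("sf2_target_sd must be > 0")
  if (cfg$beta_alpha_ratio < 0) stop("beta_alpha_ratio must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

#' Validation-cohort configuration preset
#'
#' A smaller screen: 60 lines, 9 tissues, dose grid \{2, 4, 6\} Gy.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
nci_like_config <- function(...) {
  defaults <- list(n_samples = 60L, n_tissues = 9L,
                   dose_grid = c(2, 4, 6), seed = 2L)
  override <- list(...)
  do.call(cohort_config, utils::modifyList(defaults, override))
}

# Deterministic signed effects for a set of signal genes: alternate sign in
# lexicographic gene-ID order so the gene -> effect map transfers across
# cohorts that share signal genes.
signal_effects_for <- function(signal_ids, signal_effect) {
  ids <- sort(signal_ids)
  e <- signal_effect * rep_len(c(1, -1), length(ids))
  names(e) <- ids
  e
}

#' Generate one synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param gene_ids Optional character vector of gene identifiers (length
#'   `n_genes`); defaults to `GENE_000001 ...`.
#' @param signal_gene_ids Optional identifiers of the signal genes (must be
#'   a subset of `gene_ids`); defaults to a seeded random draw.
#' @param sample_prefix Prefix for generated sample identifiers.
#' @return A list of class `radbench_cohort` with elements
#'   \describe{
#'     \item{expr}{genes x samples numeric matrix with dimnames,}
#'     \item{curves}{long-format data.frame (`sample_id`, `dose_gy`,
#'       `surviving_fraction`, `clipped`),}
#'     \item{truth}{ground truth: `signal_gene_ids`, signed `effects`,
#'       per-sample `alpha`, `beta`, `true_sf2`, `tissue`,}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_cohort <- function(config, gene_ids = NULL, signal_gene_ids = NULL,
                            sample_prefix = "S") {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  ng <- config$n_genes; ns <- config$n_samples
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE_%06d", seq_len(ng))
  stopifnot(length(gene_ids) == ng, !anyDuplicated(gene_ids))
  if (is.null(signal_gene_ids)) {
    signal_gene_ids <- sort(sample(gene_ids, config$n_signal_genes))
  }
  stopifnot(all(signal_gene_ids %in% gene_ids))
  sample_ids <- sprintf("%s_%04d", sample_prefix, seq_len(ns))

  tissue <- sample.int(config$n_tissues, ns, replace = TRUE)
  names(tissue) <- sample_ids

  # log2-like expression: gene baseline + tissue block shift + i.i.d. noise
  base_mean <- stats::rnorm(ng, mean = 6, sd = 1.5)
  tissue_shift <- matrix(stats::rnorm(ng * config$n_tissues,
                                      sd = config$tissue_effect_sd),
                         nrow = ng)
  expr <- matrix(stats::rnorm(ng * ns, sd = config$expression_noise_sd),
                 nrow = ng, dimnames = list(gene_ids, sample_ids))
  expr <- expr + base_mean
  shift <- tissue_shift[, tissue, drop = FALSE]
  expr <- expr + shift

  # latent radioresistance score: signed sum of standardized signal genes.
  # By default the tissue component of signal-gene expression is removed
  # before standardization, so tissue blocks shape expression but not SF2;
  # tissue_couples_sf2 = TRUE uses the observed expression instead.
  effects <- signal_effects_for(signal_gene_ids, config$signal_effect)
  sig <- expr[names(effects), , drop = FALSE]
  if (!config$tissue_couples_sf2) {
    sig <- sig - shift[match(names(effects), gene_ids), , drop = FALSE]
  }
  sig_std <- t(scale(t(sig)))
  sig_std[!is.finite(sig_std)] <- 0
  latent <- drop(crossprod(sig_std, effects)) + stats::rnorm(ns)

  # affine calibration on the SF2 scale, truncation to (0, 1] last
  z <- (latent - mean(latent)) / stats::sd(latent)
  sf2_raw <- config$sf2_target_mean + config$sf2_target_sd * z
  sf2_cal <- pmin(pmax(sf2_raw, 1e-4), 1)
  r <- config$beta_alpha_ratio
  alpha <- -log(sf2_cal) / (2 + 4 * r)
  beta <- r * alpha
  true_sf2 <- exp(-2 * alpha - 4 * beta)
  names(alpha) <- names(beta) <- names(true_sf2) <- sample_ids

  # observed surviving fractions with multiplicative log-normal noise
  grid <- config$dose_grid
  nd <- length(grid)
  sf_true <- exp(outer(-grid, alpha) - outer(grid^2, beta))  # doses x samples
  noise <- exp(matrix(stats::rnorm(nd * ns, sd = config$survival_noise_sd),
                      nrow = nd))
  sf_obs <- sf_true * noise
  clipped <- sf_obs > 1
  sf_obs[clipped] <- 1
  curves <- data.frame(
    sample_id = rep(sample_ids, each = nd),
    dose_gy = rep(grid, times = ns),
    surviving_fraction = as.vector(sf_obs),
    clipped = as.vector(clipped),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      expr = expr,
      curves = curves,
      truth = list(
        signal_gene_ids = signal_gene_ids,
        effects = effects,
        alpha = alpha, beta = beta, true_sf2 = true_sf2,
        tissue = tissue
      ),
      config = config
    ),
    class = "radbench_cohort"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Generate paired discovery/validation cohorts with a shared gene universe
#'
#' The two cohorts share at least `shared_gene_fraction` of their gene
#' identifiers, including all signal genes, and use the identical
#' gene-to-effect mapping so the planted signal transfers across cohorts.
#' Samples are independent (distinct identifiers, independent seeds).
#'
#' @param discovery,validation [cohort_config()] objects. Both must use the
#'   same `n_signal_genes` and `signal_effect`.
#' @param shared_gene_fraction Fraction in (0, 1] of each cohort's genes
#'   drawn from the common pool.
#' @return List with elements `discovery` and `validation`, each a
#'   `radbench_cohort`.
#' @export
generate_paired_cohorts <- function(discovery, validation,
                                    shared_gene_fraction = 1.0) {
  stopifnot(inherits(discovery, "cohort_config"),
            inherits(validation, "cohort_config"))
  if (!(shared_gene_fraction > 0 && shared_gene_fraction <= 1)) {
    stop("shared_gene_fraction must lie in (0, 1]")
  }
  if (discovery$n_signal_genes != validation$n_signal_genes ||
      discovery$signal_effect != validation$signal_effect) {
    stop("discovery and validation must share signal-gene generative parameters")
  }
  n_shared <- ceiling(shared_gene_fraction *
                      min(discovery$n_genes, validation$n_genes))
  if (discovery$n_signal_genes > n_shared) {
    stop("signal genes do not fit in the shared gene pool")
  }
  shared <- sprintf("GENE_%06d", seq_len(n_shared))
  genes_d <- c(shared, sprintf("DGENE_%06d",
                               seq_len(discovery$n_genes - n_shared)))
  genes_v <- c(shared, sprintf("VGENE_%06d",
                               seq_len(validation$n_genes - n_shared)))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(discovery$seed)
  signal <- sort(sample(shared, discovery$n_signal_genes))

  list(
    discovery = generate_cohort(discovery, gene_ids = genes_d,
                                signal_gene_ids = signal,
                                sample_prefix = "DISC"),
    validation = generate_cohort(validation, gene_ids = genes_v,
                                 signal_gene_ids = signal,
                                 sample_prefix = "VAL")
  )
}

#' Generate a gene-set collection with optionally planted enrichment
#'
#' `n_planted` sets are seeded with a majority (60%) of signal genes; the
#' remaining sets are uniform random draws from the universe. The collection
#' serializes to standard GMT via [write_gmt()].
#'
#' @param universe Character vector of gene identifiers.
#' @param signal_genes Identifiers of signal genes (subset of `universe`);
#'   may be empty when `n_planted = 0`.
#' @param signal_effects Optional named vector of signed effects (the
#'   `effects` element of a cohort's ground truth). When given, planted
#'   sets are direction-coherent: odd-numbered sets draw their signal
#'   majority from positively associated genes, even-numbered sets from
#'   negatively associated ones, mimicking pathways enriched or depleted
#'   with the phenotype.
#' @param n_sets Total number of sets (default 1498, the size of a typical
#'   curated pathway collection).
#' @param n_planted Number of sets planted with signal genes.
#' @param size_range Length-2 integer range of set sizes.
#' @param seed Integer seed.
#' @return A list of class `gene_set_collection`: named list `sets` of
#'   member-gene vectors plus a `descriptions` vector.
#' @export
generate_gene_sets <- function(universe, signal_genes = character(0),
                               n_sets = 1498L, n_planted = 0L,
                               size_range = c(15L, 200L), seed = 1L,
                               signal_effects = NULL) {
  stopifnot(n_planted <= n_sets, length(size_range) == 2L)
  if (max(size_range) > length(universe)) {
    stop("size_range exceeds the universe size")
  }
  if (n_planted > 0L && length(signal_genes) == 0L) {
    stop("planted sets require signal genes")
  }
  stopifnot(all(signal_genes %in% universe))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  non_signal <- setdiff(universe, signal_genes)
  planted_frac <- 0.6
  sets <- vector("list", n_sets)
  names(sets) <- c(
    sprintf("PLANTED_SET_%03d", seq_len(n_planted)),
    sprintf("RANDOM_SET_%04d", seq_len(n_sets - n_planted))
  )[seq_len(n_sets)]
  sizes <- sample(seq(size_range[[1]], size_range[[2]]), n_sets,
                  replace = TRUE)
  for (i in seq_len(n_sets)) {
    s <- sizes[[i]]
    if (i <= n_planted) {
      pool <- signal_genes
      if (!is.null(signal_effects)) {
        want <- if (i %% 2L == 1L) signal_effects > 0 else signal_effects < 0
        pool <- intersect(names(signal_effects)[want], signal_genes)
        if (length(pool) == 0L) pool <- signal_genes
      }
      k <- ceiling(planted_frac * s)
      if (k > length(pool)) {               # keep the signal majority
        k <- length(pool)
        s <- min(s, floor(k / planted_frac))
      }
      sets[[i]] <- c(sample(pool, k),
                     sample(non_signal, s - k))
    } else {
      sets[[i]] <- sample(universe, s)
    }
  }
  structure(
    list(
      sets = sets,
      descriptions = stats::setNames(
        ifelse(seq_len(n_sets) <= n_planted, "planted", "random"),
        names(sets)
      )
    ),
    class = "gene_set_collection"
  )
}
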