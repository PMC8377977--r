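#' Concordance-index evaluation under pre-validation and external validation
#'
#' Models are scored by the concordance index: the probability that the
#' predictor ranks a random pair of samples in the same order as the
#' observed outcome (0.5 = random, 1 = perfect). The benchmark design has
#' two phases: a pre-validation phase of 10 iterations of 10-fold
#' cross-validation on the discovery cohort, then training on the full
#' discovery cohort and testing on the independent validation cohort,
#' repeated ten times (fresh seed stream per repeat, which matters for the
#' stochastic fitters).
#'
#' @name evaluation
NULL

#' Concordance index for continuous outcomes
#'
#' Pairs with tied observations are excluded; pairs with tied predictions
#' count one half. \eqn{CI = (\#concordant + \tfrac12\,\#pred\text{-}tied)
#' / \#pairs}.
#'
#' @param pred Numeric prediction vector.
#' @param obs Numeric observed-outcome vector, same length >= 2, not all
#'   tied.
#' @return Concordance index in `[0, 1]`.
#' @export
concordance_index <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2L)
  if (any(!is.finite(pred)) || any(!is.finite(obs))) {
    stop("pred and obs must be finite")
  }
  dp <- sign(outer(pred, pred, "-"))
  do <- sign(outer(obs, obs, "-"))
  upper <- upper.tri(dp)
  dp <- dp[upper]; do <- do[upper]
  comparable <- do != 0
  if (!any(comparable)) stop("all observations tied: concordance undefined")
  dp <- dp[comparable]; do <- do[comparable]
  (sum(dp * do > 0) + 0.5 * sum(dp == 0)) / length(dp)
}

#' Build a repeated stratified cross-validation plan
#'
#' Samples are stratified by outcome deciles: within each block of
#' `n_folds` consecutive outcome-ordered samples, fold labels are dealt at
#' random, so folds partition the samples exactly once per iteration with
#' sizes differing by at most one and balanced outcome distributions.
#' Pass `stratify = FALSE` for plain random folds.
#'
#' @param y Outcome vector (used for stratification and length).
#' @param n_folds Folds per iteration (default 10).
#' @param n_iterations Iterations/repetitions (default 10).
#' @param seed Integer seed.
#' @param stratify Stratify folds by outcome order (default `TRUE`).
#' @return A list of class `cv_plan` with `folds`: a list of
#'   `n_iterations` integer vectors of fold assignments.
#' @export
cv_plan <- function(y, n_folds = 10L, n_iterations = 10L, seed = 1L,
                    stratify = TRUE) {
  n <- length(y)
  if (n < 2L * n_folds) stop("too few samples for the requested folds")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  folds <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    assign_ <- integer(n)
    if (stratify) {
      ord <- order(y, sample.int(n))          # random tie-break
      labels <- rep(seq_len(n_folds), length.out = n)
      pos <- 1L
      while (pos <= n) {
        block <- ord[pos:min(pos + n_folds - 1L, n)]
        assign_[block] <- sample(labels[pos:(pos + length(block) - 1L)])
        pos <- pos + n_folds
      }
    } else {
      assign_ <- sample(rep_len(seq_len(n_folds), n))
    }
    folds[[it]] <- assign_
  }
  structure(
    list(n_samples = n, n_folds = as.integer(n_folds),
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         stratified = isTRUE(stratify), folds = folds),
    class = "cv_plan"
  )
}

t_interval <- function(values, level = 0.95) {
  m <- mean(values)
  if (length(values) < 2L || stats::sd(values) == 0) {
    return(c(low = m, high = m))
  }
  half <- stats::qt(1 - (1 - level) / 2, df = length(values) - 1L) *
    stats::sd(values) / sqrt(length(values))
  c(low = m - half, high = m + half)
}

new_report <- function(model, phase, per_iteration, extra = list()) {
  ci <- t_interval(per_iteration)
  structure(
    c(list(model = model, phase = phase,
           mean_ci = mean(per_iteration),
           ci_low = unname(ci[["low"]]), ci_high = unname(ci[["high"]]),
           per_iteration = per_iteration), extra),
    class = "benchmark_report"
  )
}

#' Pre-validation by repeated cross-validation
#'
#' For each iteration of the plan, the model is fitted on each 9/10
#' training portion (variance prefilter, gene selection and hyperparameter
#' tuning all inside the training portion unless the spec carries a fixed
#' `prefilter_genes` list), the held-out tenth is predicted, and one
#' concordance index per iteration is computed on the pooled out-of-fold
#' prediction vector. Reports the mean and a t-based 95% confidence
#' interval over the iteration values. Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param expr Genes x samples matrix.
#' @param y Outcome vector aligned with the samples.
#' @param plan A [cv_plan()]; defaults to 10 x 10-fold on `y`.
#' @param seed Integer seed stream for stochastic fitters.
#' @return A `benchmark_report` with `per_iteration` concordance indexes.
#' @export
cross_validate <- function(spec, expr, y, plan = NULL, seed = 1L) {
  y <- align_outcome(expr, y)
  if (is.null(plan)) plan <- cv_plan(y, seed = seed)
  stopifnot(inherits(plan, "cv_plan"), plan$n_samples == length(y))
  per_iter <- numeric(plan$n_iterations)
  for (it in seq_len(plan$n_iterations)) {
    assign_ <- plan$folds[[it]]
    if (min(table(assign_)) < 2L) stop("a fold has fewer than 2 samples")
    oof <- rep(NA_real_, length(y))
    for (f in sort(unique(assign_))) {
      test <- assign_ == f
      model <- fit_predictor(spec, expr[, !test, drop = FALSE], y[!test],
                             seed = seed + 1000L * it + f)
      oof[test] <- predict(model, expr[, test, drop = FALSE])
    }
    stopifnot(!anyNA(oof))                  # folds partition the samples
    per_iter[[it]] <- concordance_index(oof, y)
  }
  new_report(spec$name, "pre_validation", per_iter,
             extra = list(seed = seed, plan = plan[c("n_folds",
                                                     "n_iterations",
                                                     "seed", "stratified")]))
}

#' External validation on an independent cohort
#'
#' Intersects the gene universes, fits on the full discovery cohort and
#' scores predictions on the validation cohort, `n_repeats` times with a
#' fresh seed per repeat (bootstrap resampling and inner-CV folds change;
#' deterministic fitters yield zero-variance repeats, which is expected
#' and reported). Validation samples never touch fitting or tuning.
#'
#' @param spec A [model_spec()].
#' @param expr_disc,y_disc Discovery expression and outcome.
#' @param expr_val,y_val Validation expression and outcome.
#' @param n_repeats Number of repeats (default 10).
#' @param seed Integer base seed.
#' @return A `benchmark_report` with `per_iteration` = per-repeat values.
#' @export
external_validate <- function(spec, expr_disc, y_disc, expr_val, y_val,
                              n_repeats = 10L, seed = 1L) {
  y_disc <- align_outcome(expr_disc, y_disc)
  y_val <- align_outcome(expr_val, y_val)
  common <- intersect(rownames(expr_disc), rownames(expr_val))
  if (length(common) == 0L) stop("empty gene intersection between cohorts")
  expr_disc <- expr_disc[common, , drop = FALSE]
  expr_val <- expr_val[common, , drop = FALSE]
  per_rep <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    model <- fit_predictor(spec, expr_disc, y_disc, seed = seed + r)
    pred <- predict(model, expr_val)
    per_rep[[r]] <- concordance_index(pred, y_val)
  }
  new_report(spec$name, "external_validation", per_rep,
             extra = list(seed = seed, n_common_genes = length(common)))
}

#' Run the full two-phase benchmark over all model configurations
#'
#' Runs [cross_validate()] on the discovery cohort and
#' [external_validate()] against the validation cohort for every supplied
#' model specification (defaults to the six standard configurations), and
#' assembles a comparison table ranked by pre-validation mean concordance.
#' Failures of individual models are caught and marked rather than
#' aborting the benchmark.
#'
#' @param expr_disc,y_disc Discovery expression matrix and outcome.
#' @param expr_val,y_val Validation expression matrix and outcome (optional;
#'   skip external validation when `NULL`).
#' @param specs Named list of [model_spec()]s (default
#'   [default_model_specs()]).
#' @param n_folds,n_iterations,n_repeats Design sizes (defaults 10/10/10).
#' @param seed Integer seed.
#' @return A list of class `benchmark_result`: `table` (one row per model
#'   and phase), `reports` (the raw `benchmark_report`s) and `provenance`.
#' @export
run_benchmark <- function(expr_disc, y_disc, expr_val = NULL, y_val = NULL,
                          specs = default_model_specs(),
                          n_folds = 10L, n_iterations = 10L,
                          n_repeats = 10L, seed = 1L) {
  y_disc <- align_outcome(expr_disc, y_disc)
  plan <- cv_plan(y_disc, n_folds = n_folds, n_iterations = n_iterations,
                  seed = seed)
  reports <- list(); rows <- list()
  for (nm in names(specs)) {
    for (phase in c("pre_validation",
                    if (!is.null(expr_val)) "external_validation")) {
      rep_ <- tryCatch({
        if (phase == "pre_validation") {
          cross_validate(specs[[nm]], expr_disc, y_disc, plan, seed = seed)
        } else {
          external_validate(specs[[nm]], expr_disc, y_disc,
                            expr_val, y_val, n_repeats, seed = seed)
        }
      }, error = function(e) e)
      if (inherits(rep_, "error")) {
        rows[[paste(nm, phase)]] <- data.frame(
          model = nm, phase = phase, mean_ci = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_,
          error = conditionMessage(rep_), stringsAsFactors = FALSE
        )
      } else {
        reports[[paste(nm, phase, sep = ".")]] <- rep_
        rows[[paste(nm, phase)]] <- data.frame(
          model = nm, phase = phase, mean_ci = rep_$mean_ci,
          ci_low = rep_$ci_low, ci_high = rep_$ci_high,
          error = NA_character_, stringsAsFactors = FALSE
        )
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  table <- table[order(table$phase, -ifelse(is.na(table$mean_ci), -Inf,
                                            table$mean_ci)), ]
  rownames(table) <- NULL
  structure(
    list(table = table, reports = reports,
         provenance = list(seed = seed, n_folds = n_folds,
                           n_iterations = n_iterations,
                           n_repeats = n_repeats,
                           n_genes = nrow(expr_disc),
                           n_discovery = ncol(expr_disc),
                           n_validation = if (is.null(expr_val)) 0L
                                          else ncol(expr_val),
                           version = as.character(
                             utils::packageVersion("radbench")))),
    class = "benchmark_result"
  )
}
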