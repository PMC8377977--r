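#' Genomic predictor families for radiosensitivity
#'
#' Five linear modelling strategies share one fit/predict contract, all
#' operating on a variance-prefiltered expression matrix and a continuous
#' SF2 outcome:
#' \describe{
#'   \item{single_gene}{univariate regression on the gene with the largest
#'     absolute Spearman correlation with SF2 (the baseline);}
#'   \item{rank_ensemble}{one univariate model per top-correlated gene, the
#'     prediction being their unweighted mean;}
#'   \item{rank_multivariate}{multivariate least squares on the same
#'     top-correlated genes (minimum-norm when rank-deficient);}
#'   \item{mrmr_exhaustive / mrmr_bootstrap}{minimum-redundancy
#'     maximum-relevance greedy selection producing K solutions, aggregated
#'     into one signature, then multivariate least squares;}
#'   \item{elastic_net}{L1/L2-penalized regression at mixing 0.5, penalty
#'     strength chosen over \eqn{\lambda = e^\gamma, \gamma \in (-6, 5)} by
#'     inner 10-fold cross-validated mean squared error.}
#' }
#' Signature-based models default to 30 genes; the prefilter keeps the 1000
#' most variable genes.
#'
#' @name predictors
NULL

#' Keep the most variable genes
#'
#' Deterministic: ties in variance are broken by lexicographic gene ID.
#'
#' @param expr Genes x samples matrix with rownames.
#' @param n_keep Number of genes to retain (1 <= n_keep <= nrow).
#' @return Character vector of the selected gene identifiers.
#' @export
variance_filter <- function(expr, n_keep) {
  if (n_keep <= 0) stop("n_keep must be positive")
  if (n_keep > nrow(expr)) stop("n_keep exceeds the number of genes")
  v <- apply(expr, 1L, stats::var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord][seq_len(n_keep)]
}

# Samples x genes matrix of centered, unit-norm mid-ranks: pairwise Spearman
# correlations are plain cross products of its columns.
ranked_columns <- function(expr) {
  rk <- apply(expr, 1L, rank)                   # samples x genes
  if (is.null(dim(rk))) rk <- matrix(rk, ncol = nrow(expr))
  rk <- scale(rk, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(rk^2))
  nrm[nrm == 0] <- 1                            # constant gene -> zero column
  rk <- sweep(rk, 2L, nrm, "/")
  colnames(rk) <- rownames(expr)
  rk
}

unit_rank_vector <- function(y) {
  ry <- rank(y) - mean(rank(y))
  n <- sqrt(sum(ry^2))
  if (n == 0) stop("outcome is constant: Spearman ranking undefined")
  ry / n
}

# |Spearman| ranking of genes vs y; ties broken by gene ID.
top_correlated_genes <- function(expr, y, k) {
  rc <- ranked_columns(expr)
  rho <- drop(crossprod(rc, unit_rank_vector(y)))
  ord <- order(-abs(rho), colnames(rc))
  list(genes = colnames(rc)[ord][seq_len(k)], rho = rho)
}

new_model <- function(name, selected_genes, coefficients, intercept,
                      hyper = list(), extra = list(), fitted_values) {
  structure(
    c(list(
      name = name,
      selected_genes = selected_genes,
      coefficients = coefficients,
      intercept = intercept,
      hyperparameters = hyper,
      fitted_values = fitted_values,
      fitted = TRUE
    ), extra),
    class = "radbench_model"
  )
}

linear_predict <- function(genes, coefficients, intercept, expr) {
  drop(intercept + crossprod(expr[genes, , drop = FALSE], coefficients))
}

#' Fit the single-gene baseline
#'
#' Selects the gene maximizing the absolute Spearman correlation with the
#' outcome and fits ordinary least squares of `y` on its expression.
#'
#' @param expr Genes x samples matrix; `y` outcome, one value per sample.
#' @param y Continuous outcome (SF2).
#' @return A fitted `radbench_model`.
#' @export
fit_single_gene <- function(expr, y) {
  y <- align_outcome(expr, y)
  if (ncol(expr) < 3L) stop("at least 3 samples required")
  sel <- top_correlated_genes(expr, y, 1L)
  if (all(abs(sel$rho) < .Machine$double.eps)) {
    stop("no gene varies with the outcome (all correlations undefined or 0)")
  }
  g <- sel$genes
  x <- expr[g, ]
  fit <- stats::lm.fit(cbind(1, x), y)
  co <- stats::setNames(fit$coefficients[[2]], g)
  new_model("single_gene", g, co, fit$coefficients[[1]],
            hyper = list(),
            fitted_values = stats::setNames(drop(fit$fitted.values),
                                            colnames(expr)))
}

#' Fit the rank-gene ensemble
#'
#' Top `signature_size` genes by absolute Spearman correlation; one
#' univariate OLS per gene; the prediction is the unweighted mean of the
#' per-gene predictions (itself a linear model).
#'
#' @inheritParams fit_single_gene
#' @param signature_size Number of genes in the signature (default 30).
#' @return A fitted `radbench_model` carrying the per-gene univariate
#'   models in `$univariate`.
#' @export
fit_rank_ensemble <- function(expr, y, signature_size = 30L) {
  y <- align_outcome(expr, y)
  if (signature_size <= 0) stop("signature_size must be positive")
  if (signature_size > nrow(expr)) stop("signature_size exceeds gene count")
  genes <- top_correlated_genes(expr, y, signature_size)$genes
  slope <- numeric(length(genes)); inter <- numeric(length(genes))
  for (i in seq_along(genes)) {
    x <- expr[genes[[i]], ]
    vx <- stats::var(x)
    b <- if (vx > 0) stats::cov(x, y) / vx else 0
    slope[[i]] <- b
    inter[[i]] <- mean(y) - b * mean(x)
  }
  k <- length(genes)
  co <- stats::setNames(slope / k, genes)
  b0 <- mean(inter)
  new_model("rank_ensemble", genes, co, b0,
            hyper = list(signature_size = signature_size),
            extra = list(univariate = data.frame(
              gene = genes, slope = slope, intercept = inter,
              stringsAsFactors = FALSE
            )),
            fitted_values = linear_predict(genes, co, b0, expr))
}

# Minimum-norm least squares of y on the rows of expr named in `genes`.
min_norm_lsq <- function(expr, genes, y) {
  X <- t(expr[genes, , drop = FALSE])
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  slopes <- if (any(pos)) {
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
  } else {
    numeric(ncol(Xc))
  }
  list(coefficients = stats::setNames(slopes, genes),
       intercept = mean(y) - sum(xbar * slopes))
}

#' Fit the rank-gene multivariate model
#'
#' Same gene selection as [fit_rank_ensemble()], followed by multivariate
#' least squares; when the design is rank-deficient (e.g. collinear genes)
#' the minimum-norm solution is used, so predictions stay defined.
#'
#' @inheritParams fit_rank_ensemble
#' @return A fitted `radbench_model`.
#' @export
fit_rank_multivariate <- function(expr, y, signature_size = 30L) {
  y <- align_outcome(expr, y)
  if (signature_size <= 0) stop("signature_size must be positive")
  if (signature_size > nrow(expr)) stop("signature_size exceeds gene count")
  genes <- top_correlated_genes(expr, y, signature_size)$genes
  ls <- min_norm_lsq(expr, genes, y)
  new_model("rank_multivariate", genes, ls$coefficients, ls$intercept,
            hyper = list(signature_size = signature_size),
            fitted_values = linear_predict(genes, ls$coefficients,
                                           ls$intercept, expr))
}

# Correlation-based mutual information I(a, b) = -0.5 * ln(1 - rho^2),
# capped where rho^2 is numerically 1.
cor_mi <- function(rho, eps = 1e-12) {
  one_minus <- 1 - rho^2
  capped <- one_minus < eps
  if (any(capped)) {
    warning(sprintf("%d correlation(s) numerically +/-1: mutual information capped",
                    sum(capped)))
    one_minus[capped] <- eps
  }
  -0.5 * log(one_minus)
}

# One greedy mRMR run: maximize relevance minus mean redundancy with the
# already-selected genes. `rc` is the ranked-columns matrix, `rel` the
# per-gene relevance. Ties broken by gene ID.
mrmr_greedy <- function(rc, rel, seed_gene, signature_size) {
  genes <- colnames(rc)
  selected <- seed_gene
  red_sum <- stats::setNames(numeric(length(genes)), genes)
  trace <- rel[[seed_gene]]
  current <- seed_gene
  while (length(selected) < signature_size) {
    rho_new <- drop(crossprod(rc, rc[, current]))
    rho_new[[current]] <- 0              # self-correlation is not redundancy
    red_new <- cor_mi(rho_new)
    red_sum <- red_sum + red_new
    crit <- rel - red_sum / length(selected)
    crit[selected] <- -Inf
    best <- genes[order(-crit, genes)][[1]]
    trace <- c(trace, crit[[best]])
    selected <- c(selected, best)
    current <- best
  }
  list(genes = selected, criterion = unname(trace))
}

#' Minimum-redundancy maximum-relevance gene selection
#'
#' Relevance and redundancy are the correlation-based mutual information
#' \eqn{\hat I(a, b) = -\tfrac12 \ln(1 - \rho_s(a, b)^2)} with
#' \eqn{\rho_s} the Spearman correlation. Each greedy step adds the gene
#' maximizing relevance to the outcome minus the mean redundancy with the
#' genes already selected.
#'
#' Two ways of producing `K` solutions:
#' \describe{
#'   \item{exhaustive}{solution j is seeded with the j-th most relevant
#'     gene (so the first selected feature of every solution is distinct)
#'     and grown greedily on the full data;}
#'   \item{bootstrap}{K resamples of the samples with replacement, classical
#'     greedy mRMR (seeded with the most relevant gene) on each.}
#' }
#' The final signature ranks genes by selection frequency across the K
#' solutions, breaking ties by mean within-solution position and then by
#' gene ID.
#'
#' @inheritParams fit_rank_ensemble
#' @param method `"exhaustive"` or `"bootstrap"`.
#' @param K Number of mRMR solutions (default 10).
#' @param seed Integer seed (used by the bootstrap resampling).
#' @return A list of class `mrmr_solution_set`: `solutions` (K ordered gene
#'   vectors), `method`, `K`, `criterion_trace`, and `signature` (the
#'   aggregated top-`signature_size` genes).
#' @export
mrmr_select <- function(expr, y, signature_size = 30L,
                        method = c("exhaustive", "bootstrap"),
                        K = 10L, seed = 1L) {
  method <- match.arg(method)
  y <- align_outcome(expr, y)
  if (K < 1L) stop("K must be >= 1")
  if (signature_size > nrow(expr)) stop("signature_size exceeds gene count")
  if (method == "exhaustive" && K > nrow(expr)) {
    stop("exhaustive method needs K distinct seed genes")
  }

  solutions <- vector("list", K)
  traces <- vector("list", K)
  if (method == "exhaustive") {
    rc <- ranked_columns(expr)
    rel <- suppressWarnings(
      cor_mi(drop(crossprod(rc, unit_rank_vector(y))))
    )
    names(rel) <- colnames(rc)
    seeds <- colnames(rc)[order(-rel, colnames(rc))][seq_len(K)]
    for (j in seq_len(K)) {
      run <- mrmr_greedy(rc, rel, seeds[[j]], signature_size)
      solutions[[j]] <- run$genes
      traces[[j]] <- run$criterion
    }
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    for (j in seq_len(K)) {
      idx <- sample.int(ncol(expr), replace = TRUE)
      eb <- expr[, idx, drop = FALSE]
      yb <- y[idx]
      rc <- ranked_columns(eb)
      rel <- suppressWarnings(
        cor_mi(drop(crossprod(rc, unit_rank_vector(yb))))
      )
      names(rel) <- colnames(rc)
      seed_gene <- colnames(rc)[order(-rel, colnames(rc))][[1]]
      run <- mrmr_greedy(rc, rel, seed_gene, signature_size)
      solutions[[j]] <- run$genes
      traces[[j]] <- run$criterion
    }
  }

  signature <- aggregate_solutions(solutions, signature_size)
  structure(
    list(solutions = solutions, method = method, K = as.integer(K),
         criterion_trace = traces, signature = signature),
    class = "mrmr_solution_set"
  )
}

# Selection-frequency aggregation of K ordered solutions into one signature.
aggregate_solutions <- function(solutions, signature_size) {
  tab <- do.call(rbind, lapply(solutions, function(s) {
    data.frame(gene = s, pos = seq_along(s), stringsAsFactors = FALSE)
  }))
  freq <- table(tab$gene)
  mean_pos <- tapply(tab$pos, tab$gene, mean)
  genes <- names(freq)
  ord <- order(-as.vector(freq), as.vector(mean_pos[genes]), genes)
  genes[ord][seq_len(min(signature_size, length(genes)))]
}

#' Fit an mRMR-selected multivariate model
#'
#' [mrmr_select()] followed by (minimum-norm) multivariate least squares on
#' the aggregated signature.
#'
#' @inheritParams mrmr_select
#' @param use_first_solution Use solution 1 alone as the signature instead
#'   of frequency aggregation (default `FALSE`).
#' @return A fitted `radbench_model` carrying the full solution set in
#'   `$mrmr`.
#' @export
fit_mrmr <- function(expr, y, signature_size = 30L,
                     method = c("exhaustive", "bootstrap"),
                     K = 10L, seed = 1L, use_first_solution = FALSE) {
  method <- match.arg(method)
  y <- align_outcome(expr, y)
  sel <- mrmr_select(expr, y, signature_size, method, K, seed)
  genes <- if (use_first_solution) sel$solutions[[1]] else sel$signature
  ls <- min_norm_lsq(expr, genes, y)
  new_model(paste0("mrmr_", method), genes, ls$coefficients, ls$intercept,
            hyper = list(signature_size = signature_size, K = K,
                         seed = seed, use_first_solution = use_first_solution),
            extra = list(mrmr = sel),
            fitted_values = linear_predict(genes, ls$coefficients,
                                           ls$intercept, expr))
}

#' Fit the elastic-net model
#'
#' Penalized linear regression at mixing `alpha_mix` (default 0.5). The
#' penalty \eqn{\lambda = e^\gamma} is chosen over `n_lambda` log-spaced
#' values with \eqn{\gamma \in} `gamma_range` by minimizing the inner
#' `inner_folds`-fold cross-validated mean squared error. Features are
#' standardized internally; coefficients are returned on the original
#' scale.
#'
#' @inheritParams fit_single_gene
#' @param alpha_mix Elastic-net mixing parameter in `[0, 1]`.
#' @param gamma_range Range of \eqn{\gamma = \log \lambda} (default
#'   `c(-6, 5)`).
#' @param n_lambda Grid size (default 100).
#' @param inner_folds Inner CV folds (default 10).
#' @param seed Integer seed for the inner fold assignment.
#' @param lambda Optional fixed penalty; skips the inner CV when given.
#' @return A fitted `radbench_model` (selected genes = nonzero
#'   coefficients at the chosen penalty).
#' @export
fit_elastic_net <- function(expr, y, alpha_mix = 0.5,
                            gamma_range = c(-6, 5), n_lambda = 100L,
                            inner_folds = 10L, seed = 1L, lambda = NULL) {
  y <- align_outcome(expr, y)
  if (stats::sd(y) == 0) {
    warning("constant outcome: returning an intercept-only model")
    return(new_model("elastic_net", character(0),
                     stats::setNames(numeric(0), character(0)), mean(y),
                     hyper = list(alpha_mix = alpha_mix, lambda = NA_real_),
                     fitted_values = stats::setNames(rep(mean(y), ncol(expr)),
                                                     colnames(expr))))
  }
  x <- t(expr)
  grid <- exp(seq(gamma_range[[2]], gamma_range[[1]], length.out = n_lambda))
  if (is.null(lambda)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(inner_folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha_mix, lambda = grid,
                            foldid = foldid, type.measure = "mse",
                            standardize = TRUE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha_mix, lambda = grid,
                          standardize = TRUE)
  }
  co <- drop(as.matrix(stats::coef(fit, s = lambda, exact = FALSE)))
  slopes <- co[-1]
  nz <- names(slopes)[slopes != 0]
  model <- new_model("elastic_net", nz,
                     stats::setNames(slopes[nz], nz), co[[1]],
                     hyper = list(alpha_mix = alpha_mix, lambda = lambda,
                                  gamma_range = gamma_range,
                                  n_lambda = n_lambda, seed = seed),
                     fitted_values = NULL)
  model$fitted_values <- stats::setNames(predict(model, expr), colnames(expr))
  model
}

#' Predict from a fitted radbench model
#'
#' @param object A fitted `radbench_model`.
#' @param expr Genes x samples matrix containing all of the model's
#'   selected genes (missing genes are an error naming the offenders).
#' @param ... Unused.
#' @return Named numeric vector of predictions, one per sample, in input
#'   column order.
#' @export
predict.radbench_model <- function(object, expr, ...) {
  if (!isTRUE(object$fitted)) stop("model is not fitted")
  missing <- setdiff(object$selected_genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("expression matrix is missing model genes: ",
         paste(missing, collapse = ", "))
  }
  if (length(object$selected_genes) == 0L) {
    return(stats::setNames(rep(object$intercept, ncol(expr)),
                           colnames(expr)))
  }
  pred <- linear_predict(object$selected_genes, object$coefficients,
                         object$intercept, expr)
  stats::setNames(pred, colnames(expr))
}

#' Specification of one predictor configuration
#'
#' A lightweight recipe consumed by [fit_predictor()],
#' [cross_validate()] and [external_validate()]. The variance prefilter is
#' applied inside each training set by default; pass `prefilter_genes` to
#' reproduce a cohort-level filter computed once on the whole discovery
#' cohort (the leakage-prone but screen-faithful variant).
#'
#' @param name One of `single_gene`, `rank_ensemble`, `rank_multivariate`,
#'   `mrmr_exhaustive`, `mrmr_bootstrap`, `elastic_net`.
#' @param signature_size Gene cap for ranking/mRMR models (default 30).
#' @param n_keep Variance-prefilter size (default 1000).
#' @param K mRMR solution count (default 10).
#' @param alpha_mix,gamma_range,n_lambda,inner_folds Elastic-net settings.
#' @param prefilter_genes Optional fixed gene list replacing the in-training
#'   variance filter.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name = c("single_gene", "rank_ensemble",
                                "rank_multivariate", "mrmr_exhaustive",
                                "mrmr_bootstrap", "elastic_net"),
                       signature_size = 30L, n_keep = 1000L, K = 10L,
                       alpha_mix = 0.5, gamma_range = c(-6, 5),
                       n_lambda = 100L, inner_folds = 10L,
                       prefilter_genes = NULL) {
  structure(
    list(name = match.arg(name), signature_size = as.integer(signature_size),
         n_keep = as.integer(n_keep), K = as.integer(K),
         alpha_mix = alpha_mix, gamma_range = gamma_range,
         n_lambda = as.integer(n_lambda), inner_folds = as.integer(inner_folds),
         prefilter_genes = prefilter_genes),
    class = "model_spec"
  )
}

#' The six benchmark configurations
#'
#' Five model families, mRMR counted twice (exhaustive and bootstrap).
#'
#' @param ... Shared overrides passed to every [model_spec()].
#' @return Named list of six `model_spec` objects.
#' @export
default_model_specs <- function(...) {
  nms <- c("single_gene", "rank_ensemble", "rank_multivariate",
           "mrmr_exhaustive", "mrmr_bootstrap", "elastic_net")
  stats::setNames(lapply(nms, function(n) model_spec(name = n, ...)), nms)
}

#' Fit a predictor from a model specification
#'
#' Applies the variance prefilter (inside the supplied training data unless
#' `spec$prefilter_genes` is set) and dispatches to the family's fitter.
#'
#' @param spec A [model_spec()].
#' @param expr Training genes x samples matrix.
#' @param y Training outcome.
#' @param seed Integer seed (bootstrap resampling, inner CV folds).
#' @return A fitted `radbench_model`.
#' @export
fit_predictor <- function(spec, expr, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  genes <- if (!is.null(spec$prefilter_genes)) {
    intersect(spec$prefilter_genes, rownames(expr))
  } else {
    variance_filter(expr, min(spec$n_keep, nrow(expr)))
  }
  ex <- expr[genes, , drop = FALSE]
  k <- min(spec$signature_size, nrow(ex))
  switch(spec$name,
    single_gene = fit_single_gene(ex, y),
    rank_ensemble = fit_rank_ensemble(ex, y, k),
    rank_multivariate = fit_rank_multivariate(ex, y, k),
    mrmr_exhaustive = fit_mrmr(ex, y, k, "exhaustive", spec$K, seed),
    mrmr_bootstrap = fit_mrmr(ex, y, k, "bootstrap", spec$K, seed),
    elastic_net = fit_elastic_net(ex, y, spec$alpha_mix, spec$gamma_range,
                                  spec$n_lambda, spec$inner_folds, seed)
  )
}
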