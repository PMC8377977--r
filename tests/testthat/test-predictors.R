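# A small fully-controlled design: n samples, named genes, y built by hand.
toy_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

test_that("variance_filter sorts by textbook variance with ID tie-break", {
  ex <- toy_matrix(10, 15, seed = 2)
  expect_setequal(variance_filter(ex, 10), rownames(ex))
  v <- apply(ex, 1, function(r) sum((r - mean(r))^2) / (ncol(ex) - 1))
  expect_identical(variance_filter(ex, 4), names(sort(-v))[1:4])
  ex2 <- rbind(ex, CONST = rep(3, 15))
  expect_false("CONST" %in% variance_filter(ex2, 10))
  ex3 <- rbind(A = ex[1, ], B = ex[1, ])  # tied variances -> ID order
  expect_identical(variance_filter(ex3, 2), c("A", "B"))
  expect_error(variance_filter(ex, 0), "positive")
  expect_error(variance_filter(ex, 11), "exceeds")
})

test_that("single-gene model picks the argmax |Spearman| gene and fits OLS", {
  ex <- toy_matrix(40, 60, seed = 3)
  y <- 2 * ex["g007", ] + 3
  m <- fit_single_gene(ex, y)
  expect_identical(m$selected_genes, "g007")
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-10)
  expect_equal(m$intercept, 3, tolerance = 1e-10)
  expect_equal(unname(predict(m, ex)), unname(y))
  # training concordance is at least that of every other single gene
  y2 <- ex["g001", ] + 0.5 * rnorm(60)
  m2 <- fit_single_gene(ex, y2)
  ci_best <- concordance_index(predict(m2, ex), y2)
  others <- vapply(rownames(ex), function(g) {
    b <- cov(ex[g, ], y2) / var(ex[g, ])
    concordance_index(b * ex[g, ], y2)
  }, numeric(1))
  expect_gte(ci_best + 1e-12, max(others))
})

test_that("rank ensemble aggregates univariate predictions", {
  ex <- toy_matrix(30, 50, seed = 4)
  y <- ex["g002", ] - ex["g005", ] + 0.1 * rnorm(50)
  m <- fit_rank_ensemble(ex, y, 5)
  # prediction equals the mean of the member univariate predictions
  member_preds <- sapply(seq_len(nrow(m$univariate)), function(i) {
    u <- m$univariate[i, ]
    u$intercept + u$slope * ex[u$gene, ]
  })
  expect_equal(unname(predict(m, ex)), unname(rowMeans(member_preds)))
  expect_equal(unname(m$fitted_values), unname(rowMeans(member_preds)))
  # signature_size = 1 degenerates to the single-gene model
  m1 <- fit_rank_ensemble(ex, y, 1)
  ms <- fit_single_gene(ex, y)
  expect_equal(predict(m1, ex), predict(ms, ex))
  expect_error(fit_rank_ensemble(ex, y, 0), "positive")
})

test_that("rank multivariate recovers exact linear signals and handles collinearity", {
  ex <- toy_matrix(20, 100, seed = 5)
  y <- ex["g001", ] - ex["g002", ]
  m <- fit_rank_multivariate(ex, y, 2)
  expect_setequal(m$selected_genes, c("g001", "g002"))
  expect_equal(unname(m$coefficients[c("g001", "g002")]), c(1, -1),
               tolerance = 1e-8)
  # duplicated gene -> rank-deficient design, minimum-norm still predicts
  ex2 <- rbind(ex, g001b = ex["g001", ])
  m2 <- fit_rank_multivariate(ex2, y, 3)
  expect_true(all(is.finite(m2$coefficients)))
  expect_equal(unname(predict(m2, ex2)), unname(y), tolerance = 1e-8)
  # nested classes: multivariate training MSE <= ensemble's on same genes
  y3 <- ex["g003", ] + 0.5 * ex["g004", ] + rnorm(100)
  me <- fit_rank_ensemble(ex, y3, 10)
  mm <- fit_rank_multivariate(ex, y3, 10)
  expect_setequal(me$selected_genes, mm$selected_genes)
  expect_lte(mean((y3 - mm$fitted_values)^2),
             mean((y3 - me$fitted_values)^2) + 1e-12)
})

test_that("gene selection is invariant to monotone transforms of one gene", {
  ex <- toy_matrix(25, 40, seed = 6)
  y <- ex["g010", ] + 0.3 * rnorm(40)
  sel1 <- fit_rank_ensemble(ex, y, 8)$selected_genes
  ex2 <- ex
  ex2["g010", ] <- exp(ex2["g010", ])      # strictly increasing transform
  sel2 <- fit_rank_ensemble(ex2, y, 8)$selected_genes
  expect_identical(sel1, sel2)
})

test_that("every mRMR greedy step attains the exhaustive criterion maximum", {
  set.seed(7)
  ex <- toy_matrix(20, 40, seed = 7)
  y <- ex["g001", ] + ex["g002", ] + rnorm(40)
  sel <- mrmr_select(ex, y, signature_size = 6, method = "exhaustive", K = 1)
  sol <- sel$solutions[[1]]
  for (step in 2:length(sol)) {
    already <- sol[seq_len(step - 1L)]
    crits <- vapply(setdiff(rownames(ex), already), function(g) {
      brute_mrmr_criterion(ex, y, g, already)
    }, numeric(1))
    expect_equal(unname(crits[sol[step]]), max(crits), tolerance = 1e-10)
  }
  # seed gene is the relevance argmax
  rel0 <- vapply(rownames(ex), function(g) {
    brute_mrmr_criterion(ex, y, g, character(0))
  }, numeric(1))
  expect_identical(sol[1], names(which.max(rel0)))
})

test_that("mRMR punishes duplicated genes and honours its contracts", {
  ex <- toy_matrix(15, 40, seed = 8)
  y <- ex["g001", ] + rnorm(40, sd = 0.2)
  ex2 <- rbind(ex, g001dup = ex["g001", ])  # perfect duplicate
  expect_warning(
    sel <- mrmr_select(ex2, y, signature_size = 5, method = "exhaustive",
                       K = 1),
    "capped"
  )
  sol <- sel$solutions[[1]]
  # the duplicate pair cannot both sit in the early selection
  expect_false(all(c("g001", "g001dup") %in% sol[1:3]))
  # exhaustive solutions have pairwise-distinct first features
  sel3 <- mrmr_select(ex, y, signature_size = 4, method = "exhaustive", K = 5)
  firsts <- vapply(sel3$solutions, `[[`, character(1), 1L)
  expect_identical(anyDuplicated(firsts), 0L)
  # bootstrap reproducibility
  b1 <- mrmr_select(ex, y, 4, "bootstrap", K = 3, seed = 11)
  b2 <- mrmr_select(ex, y, 4, "bootstrap", K = 3, seed = 11)
  expect_identical(b1, b2)
  # signature_size = 1, K = 1 reduces to the most relevant gene
  s1 <- mrmr_select(ex, y, 1, "exhaustive", K = 1)
  expect_identical(s1$signature, "g001")
})

test_that("exhaustive and bootstrap mRMR agree on an easy planted instance", {
  co <- tiny_cohort(n_samples = 120L, n_genes = 60L, n_signal = 5L,
                    effect = 3, surv_noise = 0)
  y <- co$truth$true_sf2
  a <- fit_mrmr(co$expr, y, 10, "exhaustive", K = 5, seed = 1)
  b <- fit_mrmr(co$expr, y, 10, "bootstrap", K = 5, seed = 1)
  jac <- length(intersect(a$selected_genes, b$selected_genes)) /
    length(union(a$selected_genes, b$selected_genes))
  expect_gte(jac, 0.5)
})

test_that("elastic net shrinks fully at heavy penalty and tends to OLS at light", {
  ex <- toy_matrix(5, 200, seed = 9)
  beta <- c(1, -0.5, 0.25, 0, 2)
  y <- drop(crossprod(ex, beta)) + rnorm(200, sd = 0.1)
  heavy <- fit_elastic_net(ex, y, lambda = exp(5))
  expect_length(heavy$selected_genes, 0)
  expect_equal(unname(predict(heavy, ex)), rep(mean(y), 200))
  light <- fit_elastic_net(ex, y, lambda = exp(-6))
  ols <- coef(lm(y ~ t(ex)))
  expect_lt(sqrt(sum((light$coefficients - ols[-1])^2)), 0.05)
  # support recovery of a sparse planted signal
  ex2 <- toy_matrix(300, 150, seed = 10)
  true_genes <- c("g001", "g010", "g100", "g200", "g300")
  y2 <- colSums(ex2[true_genes, ]) + rnorm(150, sd = 0.5)
  m <- fit_elastic_net(ex2, y2, seed = 12)
  expect_gte(length(intersect(m$selected_genes, true_genes)), 4L)
  # sparsity is monotone along the penalty path
  nz <- vapply(exp(seq(-6, 5, length.out = 12)), function(l) {
    length(fit_elastic_net(ex2, y2, lambda = l)$selected_genes)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
  expect_warning(fit_elastic_net(ex, rep(1, 200)), "constant outcome")
})

test_that("predict enforces the fitted contract and sample order", {
  ex <- toy_matrix(30, 40, seed = 13)
  y <- ex["g001", ] + rnorm(40, sd = 0.3)
  m <- fit_rank_multivariate(ex, y, 5)
  expect_equal(predict(m, ex), m$fitted_values)
  perm <- sample(ncol(ex))
  expect_identical(predict(m, ex[, perm]), predict(m, ex)[perm])
  expect_error(predict(m, ex[setdiff(rownames(ex), m$selected_genes[1]), ]),
               m$selected_genes[1])
  m$fitted <- FALSE
  expect_error(predict(m, ex), "not fitted")
})

test_that("fit_predictor applies the in-training prefilter and dispatches", {
  co <- tiny_cohort(n_samples = 50L, n_genes = 80L)
  y <- co$truth$true_sf2
  for (nm in names(default_model_specs())) {
    spec <- model_spec(nm, signature_size = 5L, n_keep = 40L, K = 3L,
                       n_lambda = 25L, inner_folds = 5L)
    m <- fit_predictor(spec, co$expr, y, seed = 2)
    expect_s3_class(m, "radbench_model")
    expect_true(all(m$selected_genes %in%
                    variance_filter(co$expr, 40L)))
    expect_length(predict(m, co$expr), 50L)
  }
  # a fixed prefilter list bypasses the in-training variance filter
  spec <- model_spec("rank_ensemble", signature_size = 3L,
                     prefilter_genes = rownames(co$expr)[1:10])
  m <- fit_predictor(spec, co$expr, y)
  expect_true(all(m$selected_genes %in% rownames(co$expr)[1:10]))
})
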