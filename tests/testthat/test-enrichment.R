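make_ranking <- function(scores, ids = sprintf("g%02d", seq_along(scores))) {
  names(scores) <- ids
  structure(
    list(gene_ids = ids, scores = scores,
         order = ids[order(scores, decreasing = TRUE)]),
    class = "gene_ranking"
  )
}

test_that("spearman matches the rank-difference formula and is rank-invariant", {
  expect_equal(spearman(1:5, 1:5), 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman(exp(x), y), spearman(x, y))
  expect_warning(expect_true(is.na(spearman(rep(1, 5), 1:5))), "constant")
})

test_that("rank_genes scores every non-constant gene and aligns samples", {
  co <- tiny_cohort(n_samples = 30L, n_genes = 50L)
  y <- co$truth$true_sf2
  r <- rank_genes(co$expr, y)
  expect_setequal(r$order, r$gene_ids)
  expect_equal(unname(r$scores["GENE_000001"]),
               spearman(co$expr["GENE_000001", ], y))
  # duplicated gene row -> identical score
  ex2 <- rbind(co$expr, DUP = co$expr[1, ])
  r2 <- rank_genes(ex2, y)
  expect_identical(unname(r2$scores["DUP"]), unname(r2$scores[rownames(co$expr)[1]]))
  # constant genes excluded with a message
  ex3 <- rbind(co$expr, CONST = rep(1, ncol(co$expr)))
  expect_message(r3 <- rank_genes(ex3, y), "1 constant")
  expect_false("CONST" %in% r3$gene_ids)
  expect_error(rank_genes(co$expr[, 1:2], y[1:2]), "3 aligned samples")
})

test_that("enrichment_score equals the hand-enumerated running sum", {
  # 5-gene universe, scores (5,4,3,2,1), members at ranks 1 and 3:
  # walk 5/8, 5/8-1/3, 5/8-1/3+3/8, ... -> max deviation 2/3 at rank 3
  r <- make_ranking(c(5, 4, 3, 2, 1))
  expect_equal(enrichment_score(r, c("g01", "g03")), 2 / 3)
  # brute-force agreement on random instances of size 5..50
  set.seed(7)
  for (i in 1:40) {
    N <- sample(5:50, 1)
    scores <- rnorm(N)
    r <- make_ranking(scores)
    m <- sample(2:(N - 1), 1)
    members <- sample(r$gene_ids, m)
    for (w in c(0, 1)) {
      expected <- brute_es(r$scores[r$order], r$order %in% members, w)
      expect_equal(enrichment_score(r, members, w), expected)
    }
  }
})

test_that("weight 0 reduces to the two-sample KS statistic", {
  set.seed(11)
  r <- make_ranking(rnorm(60))
  members <- sample(r$gene_ids, 15)
  hit_pos <- which(r$order %in% members)
  ks <- suppressWarnings(
    stats::ks.test(hit_pos, setdiff(seq_len(60), hit_pos))
  )$statistic
  expect_equal(abs(enrichment_score(r, members, weight_exponent = 0)),
               unname(ks))
})

test_that("ES sign flips when the ranking is negated", {
  set.seed(13)
  scores <- rnorm(40)
  r_pos <- make_ranking(scores)
  r_neg <- make_ranking(-scores)
  members <- sample(r_pos$gene_ids, 8)
  expect_equal(enrichment_score(r_neg, members),
               -enrichment_score(r_pos, members))
})

test_that("enrichment_score rejects degenerate sets", {
  r <- make_ranking(c(3, 2, 1))
  expect_error(enrichment_score(r, c("zz")), "no set member")
  expect_error(enrichment_score(r, r$gene_ids), "whole universe")
})

test_that("bh_fdr implements step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("gsea recovers planted sets with correct sign and controls the rest", {
  co <- generate_cohort(cohort_config(
    n_samples = 200L, n_genes = 400L, n_signal_genes = 10L,
    signal_effect = 3, survival_noise_sd = 0, seed = 8L
  ))
  y <- co$truth$true_sf2
  r <- rank_genes(co$expr, y)
  gs <- generate_gene_sets(rownames(co$expr), co$truth$signal_gene_ids,
                           n_sets = 60L, n_planted = 3L,
                           size_range = c(10L, 40L), seed = 6L,
                           signal_effects = co$truth$effects)
  res <- gsea(r, gs, n_perm = 1000L, min_size = 5L, max_size = 100L,
              seed = 12L)
  planted <- res[grep("^PLANTED", res$set_name), ]
  random <- res[grep("^RANDOM", res$set_name), ]
  expect_true(all(planted$fdr_q < 0.05))
  expect_gte(mean(random$fdr_q >= 0.05), 0.9)
  # direction-coherent planting: odd sets carry positively associated
  # signal genes (positive ES), even sets negatively associated ones
  expect_identical(
    stats::setNames(planted$direction, planted$set_name)[
      c("PLANTED_SET_001", "PLANTED_SET_002", "PLANTED_SET_003")],
    c(PLANTED_SET_001 = "positive", PLANTED_SET_002 = "negative",
      PLANTED_SET_003 = "positive")
  )
})

test_that("gsea is deterministic, order-invariant and filters sizes", {
  co <- tiny_cohort(n_samples = 40L, n_genes = 80L)
  y <- co$truth$true_sf2
  r <- rank_genes(co$expr, y)
  gs <- generate_gene_sets(rownames(co$expr), character(0), n_sets = 20L,
                           size_range = c(5L, 30L), seed = 2L)
  res1 <- gsea(r, gs, n_perm = 100L, min_size = 5L, max_size = 50L, seed = 3L)
  res2 <- gsea(r, gs, n_perm = 100L, min_size = 5L, max_size = 50L, seed = 3L)
  expect_identical(res1, res2)
  # relabeling: shuffling the collection leaves per-set results unchanged
  shuf <- gs
  ord <- rev(seq_along(gs$sets))
  shuf$sets <- gs$sets[ord]
  shuf$descriptions <- gs$descriptions[ord]
  res3 <- gsea(r, shuf, n_perm = 100L, min_size = 5L, max_size = 50L, seed = 3L)
  expect_identical(res1[order(res1$set_name), ],
                   res3[order(res3$set_name), ], ignore_attr = TRUE)
  # size filter drops sets and warns when nothing is retained
  expect_message(gsea(r, gs, n_perm = 100L, min_size = 5L, max_size = 10L,
                      seed = 1L), "dropped")
  expect_warning(
    expect_message(gsea(r, gs, n_perm = 100L, min_size = 79L, max_size = 80L,
                        seed = 1L), "dropped"),
    "no gene sets retained")
  expect_error(gsea(r, gs, n_perm = 10L), "n_perm")
})

test_that("observed ES does not depend on the permutation count", {
  co <- tiny_cohort(n_samples = 30L, n_genes = 60L)
  r <- rank_genes(co$expr, co$truth$true_sf2)
  gs <- generate_gene_sets(rownames(co$expr), character(0), n_sets = 10L,
                           size_range = c(5L, 20L), seed = 4L)
  res_a <- gsea(r, gs, n_perm = 100L, min_size = 3L, seed = 5L)
  res_b <- gsea(r, gs, n_perm = 400L, min_size = 3L, seed = 5L)
  a <- res_a[order(res_a$set_name), ]
  b <- res_b[order(res_b$set_name), ]
  expect_equal(a$es, b$es)
  # p-values are Monte-Carlo estimates of the same quantity; allow a few
  # binomial standard errors at the 100-permutation resolution
  expect_lt(max(abs(a$p_nominal - b$p_nominal)), 0.15)
  expect_lt(mean(abs(a$p_nominal - b$p_nominal)), 0.05)
})
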