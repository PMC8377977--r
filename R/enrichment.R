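#' Correlation-ranked gene set enrichment analysis
#'
#' Genes are ranked by the Spearman correlation between their expression and
#' SF2. For each gene set the signed enrichment score (ES) is the maximum
#' absolute deviation of a weighted Kolmogorov-Smirnov running sum over the
#' ranked list: member genes ("hits") increment the sum by
#' \eqn{|s|^w / \sum_{hits} |s|^w} and non-members decrement it by
#' \eqn{1/(N - m)}. Significance comes from gene-label permutations (the
#' correlation scores are randomly reassigned to genes), with a two-sided
#' pseudo-count p-value and Benjamini-Hochberg FDR across retained sets.
#'
#' @name enrichment
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#' Returns `NA` with a warning when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` for a degenerate input.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Rank all genes by Spearman correlation with the outcome
#'
#' Constant genes (zero variance across samples) are excluded with a
#' message reporting the count.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param y Named (or aligned) outcome vector, one value per sample.
#' @return A list of class `gene_ranking` with `gene_ids`, `scores` (the
#'   per-gene correlations) and `order` (gene ids sorted by score,
#'   descending).
#' @export
rank_genes <- function(expr, y) {
  y <- align_outcome(expr, y)
  if (ncol(expr) < 3L) stop("at least 3 aligned samples are required")
  keep <- matrixStats_rowSds(expr) > 0
  n_const <- sum(!keep)
  if (n_const > 0L) {
    message(sprintf("excluded %d constant gene(s) from the ranking", n_const))
  }
  expr <- expr[keep, , drop = FALSE]
  scores <- row_spearman(expr, y)
  ord <- order(scores, decreasing = TRUE)
  structure(
    list(gene_ids = rownames(expr), scores = stats::setNames(scores, rownames(expr)),
         order = rownames(expr)[ord]),
    class = "gene_ranking"
  )
}

# Spearman correlation of every matrix row against y, via ranked crossprod.
row_spearman <- function(expr, y) {
  rk <- t(apply(expr, 1L, rank))
  if (nrow(expr) == 1L) rk <- matrix(rk, nrow = 1L)
  rk <- rk - rowMeans(rk)
  ry <- rank(y) - mean(rank(y))
  num <- drop(rk %*% ry)
  den <- sqrt(rowSums(rk^2) * sum(ry^2))
  num / den
}

matrixStats_rowSds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
}

align_outcome <- function(expr, y) {
  if (!is.null(names(y)) && !is.null(colnames(expr))) {
    if (!all(colnames(expr) %in% names(y))) {
      stop("outcome is missing values for some expression samples")
    }
    y <- y[colnames(expr)]
  } else if (length(y) != ncol(expr)) {
    stop("outcome length does not match the number of samples")
  }
  as.numeric(y)
}

#' Signed enrichment score of one gene set
#'
#' Direct O(N) running-sum walk over the ranked list. `weight_exponent = 0`
#' reduces to the classical two-sample Kolmogorov-Smirnov statistic between
#' member and non-member rank positions.
#'
#' @param ranking A `gene_ranking` from [rank_genes()].
#' @param members Character vector of member gene identifiers; members
#'   outside the ranking universe are ignored.
#' @param weight_exponent Exponent on `|score|` for hit increments
#'   (default 1, weighted GSEA).
#' @return Signed ES in `[-1, 1]`.
#' @export
enrichment_score <- function(ranking, members, weight_exponent = 1) {
  stopifnot(inherits(ranking, "gene_ranking"))
  ord_scores <- ranking$scores[ranking$order]
  hit <- ranking$order %in% members
  m <- sum(hit)
  N <- length(ord_scores)
  if (m == 0L) stop("no set member is present in the ranking universe")
  if (m == N) stop("set covers the whole universe: miss step undefined")
  w <- abs(ord_scores)^weight_exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - m)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

# O(m) enrichment score given sorted member positions in the ranked list.
# `w_sorted` is |score|^w over the full ranked list; deviation extremes can
# only occur immediately after a hit or immediately before one.
es_from_positions <- function(pos_sorted, w_sorted, N) {
  m <- length(pos_sorted)
  h <- w_sorted[pos_sorted]
  ch <- cumsum(h) / sum(h)
  miss_step <- 1 / (N - m)
  idx <- seq_len(m)
  after <- ch - (pos_sorted - idx) * miss_step
  before <- c(0, ch[-m]) - (pos_sorted - idx) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, capped
#' at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation GSEA over a gene-set collection
#'
#' For every retained set the observed ES is compared with a null of
#' `n_perm` gene-label permutations: the ranked score vector is fixed and
#' each permutation randomly reassigns which positions count as hits. The
#' two-sided nominal p-value uses the standard pseudo-count,
#' \eqn{p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) / (1 + n_{perm})}, so it
#' never returns 0; q-values are Benjamini-Hochberg across retained sets.
#' Sets with fewer than `min_size` or more than `max_size` members inside
#' the ranking universe are dropped with a logged count. Deterministic
#' given `seed`.
#'
#' @param ranking A `gene_ranking`.
#' @param collection A `gene_set_collection` (see [generate_gene_sets()] or
#'   [read_gmt()]).
#' @param n_perm Number of permutations (>= 100; the study-scale default is
#'   10000).
#' @param min_size,max_size In-universe set-size filter (defaults 15/500;
#'   these change the tested-set count, so the drop count is messaged).
#' @param weight_exponent Hit-increment exponent, as in
#'   [enrichment_score()].
#' @param seed Integer seed for the permutation stream.
#' @return A data.frame of class `enrichment_result` with columns
#'   `set_name`, `es`, `direction`, `p_nominal`, `fdr_q`,
#'   `n_members_in_universe`, sorted by `p_nominal`.
#' @export
gsea <- function(ranking, collection, n_perm = 10000L, min_size = 15L,
                 max_size = 500L, weight_exponent = 1, seed = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"),
            inherits(collection, "gene_set_collection"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  universe <- ranking$order
  N <- length(universe)
  w_sorted <- abs(ranking$scores[universe])^weight_exponent

  member_pos <- lapply(collection$sets, function(g) {
    sort.int(match(intersect(g, universe), universe))
  })
  sizes <- lengths(member_pos)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (sum(!keep) > 0L) {
    message(sprintf("dropped %d set(s) outside size range [%d, %d]",
                    sum(!keep), min_size, max_size))
  }
  member_pos <- member_pos[keep]
  sizes <- sizes[keep]
  if (length(member_pos) == 0L) {
    warning("no gene sets retained after size filtering")
    return(empty_enrichment_result())
  }

  es_obs <- vapply(member_pos, es_from_positions, numeric(1),
                   w_sorted = w_sorted, N = N)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  exceed <- integer(length(member_pos))
  abs_obs <- abs(es_obs)
  for (b in seq_len(n_perm)) {
    # gene-label permutation: position of each gene under the relabeling
    perm <- sample.int(N)
    for (j in seq_along(member_pos)) {
      es_null <- es_from_positions(sort.int(perm[member_pos[[j]]]),
                                   w_sorted, N)
      if (abs(es_null) >= abs_obs[[j]]) exceed[[j]] <- exceed[[j]] + 1L
    }
  }
  p_nom <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    set_name = names(member_pos),
    es = unname(es_obs),
    direction = ifelse(es_obs >= 0, "positive", "negative"),
    p_nominal = unname(p_nom),
    fdr_q = unname(bh_fdr(p_nom)),
    n_members_in_universe = unname(sizes),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_nominal, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

empty_enrichment_result <- function() {
  out <- data.frame(
    set_name = character(0), es = numeric(0), direction = character(0),
    p_nominal = numeric(0), fdr_q = numeric(0),
    n_members_in_universe = integer(0), stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}
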