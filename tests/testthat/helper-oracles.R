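# Independent oracles and small fixture builders shared across test files.

# Quick planted cohort; "strong" signal = few signal genes with large
# effect, so each carries individually detectable correlation.
tiny_cohort <- function(n_samples = 60L, n_genes = 120L, n_signal = 8L,
                        effect = 2, surv_noise = 0.02, seed = 42L, ...) {
  generate_cohort(cohort_config(
    n_samples = n_samples, n_tissues = 4L, n_genes = n_genes,
    n_signal_genes = n_signal, signal_effect = effect,
    survival_noise_sd = surv_noise, seed = seed, ...
  ))
}

# O(n^2) double-loop concordance index: pairs with tied observations are
# skipped, tied predictions count one half.
brute_concordance <- function(pred, obs) {
  n <- length(pred)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (obs[i] == obs[j]) next
      den <- den + 1
      if (pred[i] == pred[j]) {
        num <- num + 0.5
      } else if ((pred[i] - pred[j]) * (obs[i] - obs[j]) > 0) {
        num <- num + 1
      }
    }
  }
  num / den
}

# Explicit running-sum enrichment score over a ranked score vector
# (descending) and a hit indicator.
brute_es <- function(scores_desc, hit, weight = 1) {
  N <- length(scores_desc)
  m <- sum(hit)
  w <- abs(scores_desc)^weight
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / (N - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Direct mRMR criterion for one candidate given already-selected genes,
# using stats::cor as the independent Spearman route.
brute_mrmr_criterion <- function(expr, y, candidate, selected) {
  mi <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b, method = "spearman"))
    -0.5 * log(max(1 - r^2, 1e-12))
  }
  rel <- mi(expr[candidate, ], y)
  if (length(selected) == 0L) return(rel)
  red <- mean(vapply(selected, function(s) mi(expr[candidate, ], expr[s, ]),
                     numeric(1)))
  rel - red
}
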