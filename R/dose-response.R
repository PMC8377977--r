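#' Linear-quadratic dose-response fitting and radiosensitivity summaries
#'
#' The clonogenic surviving fraction after a single dose \eqn{D} (Gy) is
#' modelled as \eqn{SF(D) = \exp(-\alpha D - \beta D^2)} with
#' \eqn{\alpha \ge 0} (per Gy) and \eqn{\beta \ge 0} (per Gy squared).
#' Fitting is least squares on log-survival, which is linear in
#' \eqn{(\alpha, \beta)} and therefore convex; the non-negativity
#' constraints are handled exactly by enumerating the active sets of the
#' two-parameter problem (unconstrained, \eqn{\alpha = 0}, \eqn{\beta = 0},
#' both zero) and keeping the feasible solution with the smallest residual
#' sum of squares.
#'
#' @name dose_response
NULL

#' Construct a dose-response curve for one sample
#'
#' @param sample_id Character scalar identifying the cell line.
#' @param doses Numeric vector of radiation doses in Gy, all > 0.
#' @param survival Numeric vector of surviving fractions in (0, 1], aligned
#'   with `doses`. Values marginally above 1 are clipped to 1 with a warning.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(sample_id, doses, survival) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  doses <- as.numeric(doses)
  survival <- as.numeric(survival)
  if (length(doses) != length(survival)) {
    stop("doses and survival must have equal length")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("all doses must be finite and > 0")
  }
  if (any(!is.finite(survival)) || any(survival <= 0)) {
    stop("surviving fractions must be finite and > 0")
  }
  if (any(survival > 1)) {
    warning(sprintf(
      "%d surviving fraction(s) > 1 clipped to 1 for sample %s",
      sum(survival > 1), sample_id
    ))
    survival <- pmin(survival, 1)
  }
  structure(
    list(sample_id = sample_id, doses = doses, survival = survival),
    class = "dose_response_curve"
  )
}

#' Fit the linear-quadratic model to one dose-response curve
#'
#' Minimizes \eqn{\sum_i (\log SF_i + \alpha D_i + \beta D_i^2)^2} subject to
#' \eqn{\alpha, \beta \ge 0}. Replicate measurements at the same dose are
#' retained as separate residuals. Deterministic.
#'
#' @param curve A [dose_response_curve()].
#' @return A list of class `lq_fit` with fields `alpha`, `beta`, `rss`
#'   (residual sum of squares on log-survival) and `n_points`.
#' @export
fit_lq <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  d <- curve$doses
  if (length(unique(d)) < 2L) {
    stop(sprintf(
      "sample %s: at least 2 distinct doses are required to fit",
      curve$sample_id
    ))
  }
  y <- -log(curve$survival)          # y = alpha*d + beta*d^2, y >= 0
  X <- cbind(d, d^2)

  rss_of <- function(ab) sum((y - X %*% ab)^2)
  candidates <- list()
  # unconstrained normal equations (2x2, solve directly)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ab <- tryCatch(drop(solve(XtX, Xty)), error = function(e) NULL)
  if (!is.null(ab) && all(is.finite(ab))) candidates <- c(candidates, list(ab))
  # beta = 0: y ~ d
  a1 <- sum(d * y) / sum(d^2)
  candidates <- c(candidates, list(c(max(a1, 0), 0)))
  # alpha = 0: y ~ d^2
  b1 <- sum(d^2 * y) / sum(d^4)
  candidates <- c(candidates, list(c(0, max(b1, 0))))
  candidates <- c(candidates, list(c(0, 0)))

  feasible <- Filter(function(ab) all(ab >= 0), candidates)
  rss <- vapply(feasible, rss_of, numeric(1))
  best <- feasible[[which.min(rss)]]
  structure(
    list(
      alpha = best[[1]], beta = best[[2]],
      rss = min(rss), n_points = length(d)
    ),
    class = "lq_fit"
  )
}

#' Surviving fraction predicted by a linear-quadratic fit
#'
#' @param fit An `lq_fit` (or any list with `alpha` and `beta`).
#' @param dose Dose in Gy, >= 0 (vectorized).
#' @return \eqn{\exp(-\alpha D - \beta D^2)}, in (0, 1].
#' @export
survival_at <- function(fit, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-fit$alpha * dose - fit$beta * dose^2)
}

#' Normalized area under the fitted survival curve
#'
#' Computes \eqn{\frac{1}{D_{max} - D_{min}} \int SF(D)\,dD} by adaptive
#' quadrature so the value lies in (0, 1] and is comparable across cohorts
#' with different dose grids. Set `normalize = FALSE` for the raw area.
#'
#' @param fit An `lq_fit`.
#' @param dose_range Length-2 numeric, `c(lower, upper)` in Gy with
#'   `lower < upper`, both >= 0.
#' @param normalize Divide by the range width (default `TRUE`).
#' @return Numeric scalar.
#' @export
lq_auc <- function(fit, dose_range, normalize = TRUE) {
  stopifnot(length(dose_range) == 2L)
  lo <- dose_range[[1]]; hi <- dose_range[[2]]
  if (!(lo >= 0 && hi > lo)) stop("dose_range must satisfy 0 <= lower < upper")
  area <- stats::integrate(function(D) survival_at(fit, D), lo, hi,
                           rel.tol = 1e-10)$value
  if (normalize) area / (hi - lo) else area
}

#' Per-sample radiosensitivity profiles (SF2 and AUC)
#'
#' Fits the linear-quadratic model to every curve and summarizes each line
#' by SF2 (surviving fraction at 2 Gy of the fitted model) and the
#' normalized AUC over `dose_range`. Samples whose curve cannot be fitted
#' (fewer than 2 distinct doses) are excluded with a message naming them.
#'
#' @param curves A list of [dose_response_curve()] objects, or a data.frame
#'   with columns `sample_id`, `dose_gy`, `surviving_fraction`.
#' @param dose_range Length-2 numeric range in Gy for the AUC.
#' @return A data.frame of class `radio_response_profile` with columns
#'   `sample_id`, `sf2`, `auc`, `alpha`, `beta`, `rss`.
#' @export
compute_profiles <- function(curves, dose_range = c(0, 8)) {
  if (is.data.frame(curves)) curves <- curves_from_table(curves)
  if (length(curves) == 0L) stop("no dose-response curves supplied")
  rows <- vector("list", length(curves))
  dropped <- character(0)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    fit <- tryCatch(fit_lq(cv), error = function(e) e)
    if (inherits(fit, "error")) {
      dropped <- c(dropped, sprintf("%s (%s)", cv$sample_id,
                                    conditionMessage(fit)))
      next
    }
    rows[[i]] <- data.frame(
      sample_id = cv$sample_id,
      sf2 = survival_at(fit, 2),
      auc = lq_auc(fit, dose_range),
      alpha = fit$alpha, beta = fit$beta, rss = fit$rss,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped) > 0L) {
    message(sprintf("excluded %d sample(s) failing the LQ fit: %s",
                    length(dropped), paste(dropped, collapse = "; ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) stop("all samples failed the LQ fit")
  rownames(out) <- NULL
  class(out) <- c("radio_response_profile", "data.frame")
  out
}

# Split a long-format table (sample_id, dose_gy, surviving_fraction) into
# a list of per-sample curves, preserving first-appearance order.
curves_from_table <- function(tab) {
  need <- c("sample_id", "dose_gy", "surviving_fraction")
  if (!all(need %in% names(tab))) {
    stop("curve table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(tab$sample_id)
  lapply(ids, function(id) {
    sub <- tab[tab$sample_id == id, , drop = FALSE]
    dose_response_curve(as.character(id), sub$dose_gy, sub$surviving_fraction)
  })
}
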