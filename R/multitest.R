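# Gene-wise p-value combination, Storey q-value FDR, Bonferroni thresholds,
# and candidate-set enrichment.

#' Fisher's combined probability test
#'
#' Combines independent p-values as X = -2 * sum(log p), referred to a
#' chi-squared distribution with 2k degrees of freedom.  Zero p-values are
#' clamped to `eps` before the logarithm (flagged via a warning).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param eps clamp for p = 0 (default 1e-300).
#' @return the combined p-value.
#' @examples
#' fisherCombine(c(0.1, 0.1))  # ~ 0.0561
#' @export
fisherCombine <- function(p, eps = 1e-300) {
  if (!length(p)) stop("empty p-value list")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0,1]")
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to ", eps)
    p[p == 0] <- eps
  }
  X <- -2 * sum(log(p))
  pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by smoothing the tail-count estimator
#' over a lambda grid (natural cubic smoothing spline, df = 3, evaluated at
#' the largest lambda, capped to (0, 1]), then converts p-values to
#' q-values: `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`.
#'
#' @param p numeric vector of p-values (a warning is issued below 100,
#'   where pi0 estimation is unstable).
#' @param lambda grid for pi0 estimation (default `seq(0, 0.90, 0.05)`).
#' @param pi0 optionally fix pi0 rather than estimating it.
#' @return list with `qvalues` (same order as `p`) and `pi0`.
#' @export
qvalueStorey <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
  m <- length(p)
  if (!m) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0,1]")
  if (m < 100) warning("fewer than 100 p-values: pi0 estimate may be unstable")
  if (is.null(pi0)) {
    if (m < 2 || length(unique(lambda)) < 4) {
      pi0 <- 1
    } else {
      pi0Lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0Lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  ranked <- p[o] * m * pi0 / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  qvalues <- numeric(m)
  qvalues[o] <- pmin(q, 1)
  list(qvalues = qvalues, pi0 = pi0)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param mEff number of (effective) independent tests.
#' @return the threshold `alpha / mEff`, with attribute `"rounded"` giving
#'   the 2-significant-figure form used in reporting.
#' @examples
#' bonferroniThreshold(0.05, 5377)  # 9.3e-06 at 2 s.f.
#' @export
bonferroniThreshold <- function(alpha = 0.05, mEff) {
  if (mEff < 1) stop("mEff must be >= 1")
  th <- alpha / mEff
  structure(th, rounded = signif(th, 2))
}

#' Candidate-set enrichment chi-square
#'
#' Tests whether a candidate gene list contains more units significant at
#' some level than expected from the screen-wide rate: expected significant
#' candidates = `nCandidates * kSignifAll / nAll`; 1-df chi-square over the
#' significant/non-significant split of the candidate list.
#'
#' @param kSignifCandidates observed significant candidates.
#' @param nCandidates candidate list size.
#' @param kSignifAll significant units in the whole screen.
#' @param nAll screen size.
#' @return list with `chi2`, `p`, `expected`.
#' @export
enrichmentChisq <- function(kSignifCandidates, nCandidates, kSignifAll, nAll) {
  stopifnot(kSignifCandidates >= 0, nCandidates >= kSignifCandidates,
            kSignifAll >= 0, nAll >= kSignifAll, nCandidates <= nAll)
  expected <- nCandidates * kSignifAll / nAll
  if (expected <= 0 || expected >= nCandidates)
    stop("degenerate expected count")
  O <- c(kSignifCandidates, nCandidates - kSignifCandidates)
  E <- c(expected, nCandidates - expected)
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       expected = expected)
}
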