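#' Beta-binomial boundary enrichment test
#'
#' Tail probability of observing at least `n_c` clipped reads among `n_t`
#' reads overlapping an exon boundary, under a beta-binomial null whose
#' parameters are the genome-wide clip totals: `alpha = N_c`,
#' `beta = N_t - N_c + 1`. The tail is
#' \deqn{P(X \ge n_c) = 1 - \sum_{x=0}^{n_c-1} {n_t \choose x}
#'   \frac{B(\alpha + x, n_t - x + \beta)}{B(\alpha, \beta)}}
#' computed in log space via a probability-mass ratio recurrence with a
#' reverse cumulative sum, so very small tails keep full relative precision.
#'
#' `n_c = 0` returns 1 by convention (no clip evidence is never significant).
#' A clip-free background (`alpha = 0`) is a degenerate null; for `n_c > 0`
#' alpha is clamped to 0.5 (half-count pseudocount) with a warning, which
#' preserves the ranking of boundaries.
#'
#' @param n_t total reads overlapping the boundary (scalar count).
#' @param n_c clipped + rescued reads supporting a junction at the boundary;
#'   vectorised.
#' @param bg a [background_model] (or any list with `alpha` and `beta`).
#' @return numeric vector of tail probabilities, one per `n_c`.
#' @seealso [build_background()], [combine_exon_pvalues()]
#' @examples
#' bg <- list(alpha = 1, beta = 1)
#' boundary_pvalue(1, 1, bg)   # 0.5: B(1,2)/B(1,1) mass at x = 0
#' @export
boundary_pvalue <- function(n_t, n_c, bg) {
  stopifnot(length(n_t) == 1L, n_t >= 0, all(n_c >= 0), all(n_c <= n_t))
  alpha <- bg$alpha
  beta <- bg$beta
  stopifnot(alpha >= 0, beta >= 1)
  out <- rep(1, length(n_c))
  if (n_t == 0L || all(n_c == 0L)) return(out)
  if (alpha == 0) {
    warning("clip-free background (alpha = 0): clamping alpha to 0.5")
    alpha <- 0.5
  }
  surv <- bb_survival(n_t, alpha, beta) # P(X >= k) for k = 0..n_t
  pos <- n_c > 0L
  out[pos] <- surv[n_c[pos] + 1L]
  out
}

## Full survival function P(X >= k), k = 0..n_t, of the beta-binomial with
## parameters (n_t, alpha, beta). The pmf is built from the ratio recurrence
##   pmf(x+1)/pmf(x) = (n_t - x)/(x + 1) * (alpha + x)/(beta + n_t - x - 1)
## in log space, then summed from the upper tail so small survival values are
## not lost to cancellation in 1 - cdf.
bb_survival <- function(n_t, alpha, beta) {
  lp0 <- lbeta(alpha, n_t + beta) - lbeta(alpha, beta)
  if (n_t == 0L) return(1)
  x <- 0:(n_t - 1L)
  lratio <- log(n_t - x) - log(x + 1) + log(alpha + x) - log(beta + n_t - x - 1)
  lpmf <- lp0 + c(0, cumsum(lratio))         # log pmf at x = 0..n_t
  m <- max(lpmf)
  pmf <- exp(lpmf - m)
  surv <- rev(cumsum(rev(pmf))) * exp(m)
  surv[1L] <- 1                              # exact by definition
  pmin(surv, 1)
}

#' Combine the two boundary p-values of an exon (harmonic mean)
#'
#' The two boundaries of an exon are tested on overlapping read sets, so
#' their p-values are dependent; the unweighted harmonic-mean p-value
#' `2 / (1/p_left + 1/p_right)` is used to combine them. Exact zeros are
#' clamped to the smallest positive double with a warning.
#'
#' @param p_left,p_right boundary tail probabilities in (0, 1]; vectorised.
#' @return combined p-values.
#' @examples
#' combine_exon_pvalues(0.01, 1)  # 2/101
#' @export
combine_exon_pvalues <- function(p_left, p_right) {
  p <- cbind(p_left, p_right)
  if (any(p == 0)) {
    warning("p-value of exactly 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stopifnot(all(p > 0), all(p <= 1))
  unname(2 / (1 / p[, 1L] + 1 / p[, 2L]))
}

## Unweighted harmonic-mean p-value of k >= 1 values; used to combine
## exon-level p-values into a transcript-level screen statistic.
hmp <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  length(p) / sum(1 / p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across the family of combined exon p-values,
#' order-preserving with the input. Thin wrapper over
#' [stats::p.adjust()] kept as the module surface for the correction step.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order and length as the input.
#' @export
adjust_qvalues <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus of clipped overhang sequences
#'
#' Overhangs are oriented so position 1 is the base adjacent to the clip
#' junction moving away from the exon. Per column, among overhangs long
#' enough to reach it, the base with frequency >= 0.80 joins the consensus;
#' the consensus stops at the first column where no base reaches 0.80 and may
#' be empty.
#'
#' @param overhangs character vector of overhang sequences (at least one).
#' @param min_freq column frequency needed to call a consensus base (0.80).
#' @return a single consensus string (possibly "").
#' @examples
#' build_consensus(c("ACG", "ACG", "ACT", "AC"))  # "AC"
#' @export
build_consensus <- function(overhangs, min_freq = 0.80) {
  overhangs <- overhangs[!is.na(overhangs) & nzchar(overhangs)]
  if (length(overhangs) == 0L) return("")
  maxlen <- max(nchar(overhangs))
  cons <- character(0)
  for (i in seq_len(maxlen)) {
    col <- substring(overhangs[nchar(overhangs) >= i], i, i)
    tab <- table(col)
    top <- which.max(tab)
    if (tab[[top]] / length(col) >= min_freq) {
      cons <- c(cons, names(tab)[top])
    } else break
  }
  paste(cons, collapse = "")
}
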