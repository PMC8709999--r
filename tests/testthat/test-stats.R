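## Beta-binomial tail, harmonic-mean combination, BH adjustment, consensus
## building and the rounding convention.

## independent oracle: direct summation of the upper-tail pmf with exact
## log-Beta arithmetic (no recurrence; arithmetically distinct route from
## the implementation)
bb_oracle <- function(nt, nc, a, b) {
  x <- nc:nt
  sum(exp(lchoose(nt, x) + lbeta(a + x, nt - x + b) - lbeta(a, b)))
}

test_that("boundary tail probability matches analytic and oracle values", {
  ## n_t = 1, n_c = 1, alpha = beta = 1: P = B(1,2)/B(1,1) = 1/2 analytically
  expect_equal(boundary_pvalue(1, 1, list(alpha = 1, beta = 1)), 0.5)
  ## n_c = 0 is never significant by convention
  expect_equal(boundary_pvalue(10, 0, list(alpha = 5, beta = 100)), 1)
  ## frozen oracle values
  expect_equal(boundary_pvalue(100, 10, list(alpha = 50, beta = 9951)),
               2.407654436982e-10, tolerance = 1e-9)
  expect_equal(boundary_pvalue(50, 5, list(alpha = 2, beta = 99)),
               1.593108263621e-02, tolerance = 1e-9)
})

test_that("tail probability agrees with the direct-summation oracle on a grid", {
  regimes <- list(c(2, 99), c(50, 9951), c(1, 1), c(10, 11), c(500, 100001))
  set.seed(11)
  for (ab in regimes) {
    for (nt in sample(1:300, 12)) {
      bg <- list(alpha = ab[1], beta = ab[2])
      nc <- unique(pmin(nt, c(1L, 2L, sample.int(nt, min(nt, 4L)))))
      p_impl <- boundary_pvalue(nt, nc, bg)
      p_orac <- vapply(nc, bb_oracle, numeric(1), nt = nt, a = ab[1], b = ab[2])
      expect_equal(p_impl, p_orac, tolerance = 1e-9)
    }
  }
})

test_that("tail probability is monotone in the evidence and the background", {
  bg <- list(alpha = 20, beta = 1000)
  p <- boundary_pvalue(80, 1:80, bg)
  expect_true(all(diff(p) <= 1e-12))           # non-increasing in n_c
  ## smaller background clip fraction makes the same counts more surprising
  p_hi <- boundary_pvalue(100, 10, list(alpha = 50, beta = 951))
  p_lo <- boundary_pvalue(100, 10, list(alpha = 5, beta = 996))
  expect_lt(p_lo, p_hi)
  ## probabilities stay in [0, 1]
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate clip-free background clamps alpha with a warning", {
  expect_warning(p <- boundary_pvalue(10, 2, list(alpha = 0, beta = 11)),
                 "clip-free")
  expect_true(p > 0 && p < 1)
  ## n_c = 0 under the degenerate null needs no clamp
  expect_silent(expect_equal(boundary_pvalue(10, 0, list(alpha = 0, beta = 11)), 1))
})

test_that("harmonic-mean combination of two boundary p-values", {
  expect_equal(combine_exon_pvalues(0.01, 0.01), 0.01)
  expect_equal(combine_exon_pvalues(0.01, 1.0), 2 / 101)
  ## symmetric
  expect_equal(combine_exon_pvalues(0.003, 0.7),
               combine_exon_pvalues(0.7, 0.003))
  ## vectorised
  expect_equal(combine_exon_pvalues(c(0.01, 0.5), c(1, 0.5)),
               c(2 / 101, 0.5))
  expect_warning(p0 <- combine_exon_pvalues(0, 0.5), "clamped")
  expect_gt(p0, 0)
})

test_that("BH adjustment is the standard step-up with monotonicity", {
  expect_equal(adjust_qvalues(rep(0.04, 5)), rep(0.04, 5))   # fixed point
  expect_equal(adjust_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_qvalues(0.2), 0.2)                     # m = 1
  expect_identical(adjust_qvalues(numeric(0)), numeric(0))
  ## order-preserving with input
  p <- c(0.04, 0.001, 0.2)
  expect_equal(adjust_qvalues(p), stats::p.adjust(p, "BH"))
})

test_that("overhang consensus uses the 80% column rule", {
  expect_equal(build_consensus(c("ACG", "ACG", "ACT", "AC")), "AC")
  expect_equal(build_consensus("TTAA"), "TTAA")
  expect_equal(build_consensus(c("A", "C")), "")
  ## exactly 80% qualifies; column support shrinks with overhang length
  expect_equal(build_consensus(c("AG", "AG", "AG", "AG", "AT")), "AG")
  expect_equal(build_consensus(c("AG", "AG", "AG", "AT")), "A")
})

test_that("nint and the removal-count formula round halves away from zero", {
  expect_identical(nint(c(0.5, 1.5, 2.4, -0.5, -1.5)),
                   c(1L, 2L, 2L, -1L, -2L))
  expect_identical(ambiguous_removal_count(10, 30, 20), 5L)
  expect_identical(ambiguous_removal_count(0, 30, 20), 0L)
  expect_identical(ambiguous_removal_count(1, 3, 2), 1L)  # 0.5 rounds up
  expect_identical(ambiguous_removal_count(0, 0, 10), 0L) # no unambiguous
})
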