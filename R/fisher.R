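#' Vectorised two-sided Fisher exact test for 2x2 count tables
#'
#' Computes the two-sided Fisher exact p-value for each table
#' `[[meth_a, unmeth_a], [meth_b, unmeth_b]]` by full enumeration of the
#' conditional hypergeometric distribution: the p-value is the sum of
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table, using a small relative
#' tolerance on the comparison to absorb floating-point ties. This is the
#' same convention as [stats::fisher.test()], but vectorised over many
#' tables.
#'
#' @param meth_a,unmeth_a,unmeth_b,meth_b integer vectors of equal length,
#'   the cell counts per table (condition A in the first row).
#' @param rel_tol relative tolerance on the probability comparison
#'   (default `1e-7`).
#' @return numeric vector of two-sided p-values in `[0, 1]`.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)   # strongly unbalanced: ~1.08e-5
#' fisher_exact_2x2(5, 5, 5, 5)     # identical proportions: 1
#' @export
fisher_exact_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b,
                             rel_tol = 1e-7) {
  n <- length(meth_a)
  if (length(unmeth_a) != n || length(meth_b) != n || length(unmeth_b) != n)
    stopf("all four count vectors must have equal length")
  if (any(c(meth_a, unmeth_a, meth_b, unmeth_b) < 0, na.rm = TRUE))
    stopf("negative counts are not a valid 2x2 table")
  p <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- meth_a[i] + unmeth_a[i]
    r2 <- meth_b[i] + unmeth_b[i]
    k <- meth_a[i] + meth_b[i]            # methylated-column margin
    if (r1 == 0L || r2 == 0L || k == 0L || k == r1 + r2) {
      p[i] <- 1
      next
    }
    support <- max(0L, k - r2):min(k, r1)
    pmf <- stats::dhyper(support, r1, r2, k)
    pobs <- pmf[match(meth_a[i], support)]
    p[i] <- min(1, sum(pmf[pmf <= pobs * (1 + rel_tol)]))
  }
  p
}
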