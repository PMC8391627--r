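#' Over-representation (ORA) hypergeometric test
#'
#' The unweighted comparator: upper-tail probability of observing at least
#' v QTL-hit genes in a size-n set under the hypergeometric null. This is
#' the style of test used by count-only QTL enrichment approaches; it
#' ignores the DE scores entirely.
#'
#' @param v observed number of distinct QTL-hit genes in the set.
#' @param N universe size.
#' @param V QTL-covered genes in the universe.
#' @param n gene-set size.
#' @return One-sided p-value \eqn{P[N_{GQ} \ge v]}.
#' @export
ora_hypergeom_test <- function(v, N, V, n) {
  check_hyper_params(N, V, n)
  if (v < 0 || v > min(n, V)) stop("v must satisfy 0 <= v <= min(n, V)")
  stats::phyper(v - 1, V, N - V, n, lower.tail = FALSE)
}

#' Gene-sampling permutation test for the pair-count statistic
#'
#' An empirical comparator: the null distribution of the gene-by-QTL pair
#' count (NQHits) is built by drawing uniform n-subsets of the universe
#' without replacement, with add-one smoothing,
#' \eqn{p = (1 + \#\{b : NQHits_b \ge obs\}) / (B + 1)}.
#' This is a labelled stand-in for sampling-based count tests, not a
#' bit-compatible reproduction of any historical implementation.
#'
#' @param universe a \code{\link{gene_universe}}.
#' @param qtls a \code{\link{qtl_set}}.
#' @param n gene-set size.
#' @param observed_nqhits the observed pair count for the tested set.
#' @param B number of draws (warns below 100).
#' @param seed optional integer seed for the draws.
#' @param mode overlap mode, see \code{\link{overlaps}}.
#' @return List with \code{p_value}, \code{B} and \code{seed}.
#' @export
gene_sampling_test <- function(universe, qtls, n, observed_nqhits, B = 1000L,
                               seed = NULL, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  N <- nrow(universe)
  if (n > N) stop("gene-set size n exceeds the universe size")
  if (B < 100) warning("B < 100 draws gives a very coarse empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  counts <- overlap_counts(universe, qtls, mode)
  null_stat <- vapply(seq_len(B), function(b) sum(counts[sample.int(N, n)]),
                      numeric(1))
  p <- (1 + sum(null_stat >= observed_nqhits)) / (B + 1)
  list(p_value = p, B = as.integer(B), seed = seed)
}
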