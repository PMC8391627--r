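#' Mean and population variance of the DE scores in a gene set
#'
#' @param d non-negative score values of the genes in the set.
#' @return List with \code{EX} (mean) and \code{VX} (population variance,
#'   denominator n). The population form pairs with the finite-population
#'   \eqn{n-1} factor in the analytic variance of the enrichment statistic.
#' @export
score_summary <- function(d) {
  if (!length(d)) stop("gene set is empty")
  EX <- mean(d)
  VX <- mean((d - EX)^2)
  list(EX = EX, VX = VX)
}

#' Score-weighted QTL enrichment statistic
#'
#' The contrast between summed DE scores of QTL-hit and non-hit genes.
#' The default \code{within_set} form contrasts hit vs non-hit genes inside
#' the gene set G,
#' \deqn{S = \sum_{i \in G, hit} D_i - \sum_{i \in G, \neg hit} D_i,}
#' which is the form whose analytic null moments are
#' \code{\link{e_sdgq}} / \code{\link{v_sdgq}}. The \code{literal} form
#' contrasts the hit genes of G against the hit genes of the complement
#' \eqn{G^c}; its null moments are not analytic and are estimated by
#' permutation inside \code{\link{qtl_gse}}.
#'
#' @param G character vector of gene ids in the set.
#' @param flags named 0/1 QTL-hit flags over the whole universe.
#' @param scores named non-negative DE scores over the whole universe.
#' @param form \code{"within_set"} (default) or \code{"literal"}.
#' @return The statistic (a single number).
#' @export
sdgq <- function(G, flags, scores, form = c("within_set", "literal")) {
  form <- match.arg(form)
  if (!length(G)) stop("gene set is empty")
  bad <- setdiff(G, names(scores))
  if (length(bad))
    stop("gene set ids missing from scores: ",
         paste(utils::head(bad, 10), collapse = ", "))
  dG <- scores[G]
  hG <- flags[G] > 0
  if (form == "within_set") {
    sum(dG[hG]) - sum(dG[!hG])
  } else {
    Gc <- setdiff(names(scores), G)
    if (!length(Gc))
      stop("literal form needs a non-empty complement (G is the whole universe)")
    dC <- scores[Gc]
    hC <- flags[Gc] > 0
    sum(dG[hG]) - sum(dC[hC])
  }
}

#' Analytic null moments of the within-set enrichment statistic
#'
#' Under the competitive null the number of hit genes in G is
#' hypergeometric and hit status is placed uniformly within G, giving
#' \deqn{E(S) = 2 E(X) E(N_{GQ}) - n E(X)}
#' \deqn{V(S) = 4\left[\frac{V(X)}{n-1}\left(E(N_{GQ})(n - E(N_{GQ})) -
#'   V(N_{GQ})\right) + E(X)^2 V(N_{GQ})\right]}
#' where \eqn{E(X), V(X)} are the mean and population variance of the
#' scores in G.
#'
#' @param EX,VX score mean and population variance in G
#'   (\code{\link{score_summary}}).
#' @param N universe size; \code{V} QTL-covered genes in the universe;
#'   \code{n} gene-set size.
#' @param V number of QTL-covered genes in the universe.
#' @param n gene-set size.
#' @return The expected value / variance of the statistic under the null.
#' @export
e_sdgq <- function(EX, N, V, n) {
  2 * EX * ngq_mean(N, V, n) - n * EX
}

#' @rdname e_sdgq
#' @export
v_sdgq <- function(EX, VX, N, V, n) {
  if (n < 2) stop("gene-set size must be at least 2 for the null variance")
  e_ngq <- ngq_mean(N, V, n)
  v_ngq <- ngq_var(N, V, n)
  out <- 4 * (VX / (n - 1) * (e_ngq * (n - e_ngq) - v_ngq) + EX^2 * v_ngq)
  if (out <= 0)
    stop("degenerate null variance (", format(out), ") for EX=", format(EX),
         ", VX=", format(VX), ", N=", N, ", V=", V, ", n=", n,
         "; scores may be all zero")
  out
}

#' Z score and one-sided p-value
#'
#' @param S observed statistic; \code{E}, \code{V} its null mean and
#'   variance.
#' @param E null expected value.
#' @param V null variance (must be positive).
#' @return \code{z_statistic}: \eqn{(S-E)/\sqrt{V}}. \code{z_pvalue}: the
#'   upper-tail standard normal probability (the alternative is one-sided:
#'   genes in G overlap QTLs more often than genes in \eqn{G^c}).
#' @export
z_statistic <- function(S, E, V) {
  if (any(V <= 0)) stop("null variance must be positive")
  (S - E) / sqrt(V)
}

#' @rdname z_statistic
#' @param z Z score(s).
#' @export
z_pvalue <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

# Permutation moments of the literal-form statistic: E and V of S over
# uniformly random n-subsets of the universe.
perm_moments_literal <- function(flags, scores, n, B = 2000L) {
  N <- length(scores)
  ids <- names(scores)
  s <- vapply(seq_len(B), function(b) {
    idx <- sample.int(N, n)
    sdgq(ids[idx], flags, scores, form = "literal")
  }, numeric(1))
  list(E = mean(s), V = stats::var(s))
}
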