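#' Hypergeometric null for the QTL-hit count of a random gene set
#'
#' Under the competitive null, QTL-hit status is distributed randomly across
#' the ranked gene list, so the number of hit genes in a size-n set drawn
#' from a universe of N genes of which V are QTL-covered follows a
#' hypergeometric distribution:
#' \deqn{P[N_{GQ}=v] = \binom{V}{v}\binom{N-V}{n-v} / \binom{N}{n}.}
#' Binomial coefficients are evaluated in log space so genome-scale N
#' (tens of thousands) does not overflow.
#'
#' @param v observed hit count(s); values outside the support have
#'   probability 0.
#' @param N universe size.
#' @param V number of QTL-covered genes in the universe.
#' @param n gene-set size.
#' @return \code{ngq_pmf}: probability vector; \code{ngq_mean} /
#'   \code{ngq_var}: the analytic mean \eqn{nV/N} and variance
#'   \eqn{nV(N-V)(N-n)/((N-1)N^2)}.
#' @examples
#' ngq_pmf(1, N = 5, V = 2, n = 2)   # 0.6
#' ngq_mean(N = 100, V = 20, n = 10) # 2
#' @export
ngq_pmf <- function(v, N, V, n) {
  check_hyper_params(N, V, n)
  p <- numeric(length(v))
  ok <- v >= max(0, n - (N - V)) & v <= min(n, V) & v == round(v)
  if (any(ok))
    p[ok] <- exp(lchoose(V, v[ok]) + lchoose(N - V, n - v[ok]) - lchoose(N, n))
  p
}

#' @rdname ngq_pmf
#' @export
ngq_mean <- function(N, V, n) {
  check_hyper_params(N, V, n)
  as.numeric(n) * as.numeric(V) / as.numeric(N)
}

#' @rdname ngq_pmf
#' @export
ngq_var <- function(N, V, n) {
  check_hyper_params(N, V, n)
  if (N == 1) stop("variance undefined for a universe of size 1")
  N <- as.numeric(N); V <- as.numeric(V); n <- as.numeric(n)
  n * V * (N - V) * (N - n) / ((N - 1) * N^2)
}

check_hyper_params <- function(N, V, n) {
  if (length(N) != 1 || length(V) != 1 || length(n) != 1 ||
      anyNA(c(N, V, n)) || N < 1 || V < 0 || V > N || n < 1 || n > N ||
      any(c(N, V, n) != round(c(N, V, n))))
    stop("invalid hypergeometric parameters: need integers 0 <= V <= N, 1 <= n <= N ",
         "(got N=", N, ", V=", V, ", n=", n, ")")
  invisible(TRUE)
}
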