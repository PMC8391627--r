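#' Hochberg step-up adjusted p-values
#'
#' Family-wise error control across the K nested gene sets, all treated as
#' equally important. Adjusted values follow the step-up recursion from the
#' largest p-value down:
#' \eqn{\tilde p_{(K)} = p_{(K)}};
#' \eqn{\tilde p_{(i)} = \min(\tilde p_{(i+1)}, (K-i+1)\,p_{(i)})},
#' capped at 1 (computed via \code{stats::p.adjust}).
#'
#' @param p p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
hochberg_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "hochberg")
}

#' Hochberg step-up rejection decisions
#'
#' The decision form of the procedure: on the ascending sort
#' \eqn{p_{(1)} \le \dots \le p_{(K)}}, find the largest i with
#' \eqn{p_{(i)} \le \alpha/(K-i+1)} and reject hypotheses 1..i. Equivalent
#' to \code{\link{hochberg_adjust}(p) <= alpha}.
#'
#' @param p p-values.
#' @param alpha significance level in (0, 1).
#' @return Logical rejection decisions in the input order.
#' @export
hochberg_reject <- function(p, alpha = 0.05) {
  check_pvalues(p)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  K <- length(p)
  ord <- order(p)
  ps <- p[ord]
  crit <- alpha / (K - seq_len(K) + 1)
  hits <- which(ps <= crit)
  reject_sorted <- rep(FALSE, K)
  if (length(hits)) reject_sorted[seq_len(max(hits))] <- TRUE
  out <- logical(K)
  out[ord] <- reject_sorted
  out
}

#' Benjamini-Hochberg FDR values
#'
#' Step-up FDR-adjusted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} K p_{(j)} / j}, capped at 1 (via
#' \code{stats::p.adjust}). Reported as the FDR column of the result table.
#'
#' @param p p-values.
#' @return FDR values in the input order.
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

check_pvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  invisible(p)
}
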