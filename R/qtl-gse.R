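#' Score-weighted QTL enrichment test over nested gene sets
#'
#' The main fitting function. Genes are ranked by their non-negative DE
#' scores; thresholds realised as gene-set sizes carve nested sets
#' \eqn{G_1 \subset \dots \subset G_K} off the top of the list; each set is
#' tested for QTL enrichment with the score-weighted statistic
#' (\code{\link{sdgq}}), standardised by its analytic hypergeometric-null
#' moments (\code{\link{e_sdgq}}, \code{\link{v_sdgq}}) into a Z score with
#' a one-sided upper-tail p-value. The K p-values are Hochberg-adjusted and
#' BH FDR values attached.
#'
#' @param universe a \code{\link{gene_universe}}.
#' @param qtls a \code{\link{qtl_set}}; must cover at least one and not all
#'   universe genes, otherwise the competitive null is degenerate and the
#'   test refuses.
#' @param scores named non-negative DE score vector covering exactly the
#'   universe gene ids (e.g. from \code{\link{nb_lrt_scores}},
#'   \code{\link{t_scores}} or \code{\link{read_scores}}).
#' @param sizes strictly increasing gene-set sizes; default 200, 300, ...,
#'   2000. Sizes equal to the universe size are refused (empty complement).
#' @param mode overlap mode, see \code{\link{overlaps}}.
#' @param form \code{"within_set"} (default; analytic moments) or
#'   \code{"literal"} (complement-contrast; permutation moments, see
#'   \code{B_perm}).
#' @param normalize_scores divide the score vector by its maximum before
#'   testing. The Z score is scale-invariant, so this changes nothing
#'   statistically; it exists for numerical hygiene with very large LRT
#'   values. Default off.
#' @param alpha significance level used by \code{summary} and \code{plot}.
#' @param baselines append ORA (\code{ora_p}) and gene-sampling
#'   (\code{sampling_p}) baseline columns.
#' @param B_perm permutation draws for literal-form moments.
#' @param B_sampling draws for the gene-sampling baseline.
#' @param seed integer seed for the permutation/sampling draws (the
#'   analytic within-set test itself is deterministic).
#' @return An object of class \code{"qtl_gse"}: a list with the per-set
#'   result table \code{$results} (columns \code{size}, \code{NGQ},
#'   \code{NQHits}, \code{V}, \code{N}, \code{SDGQ}, \code{E_SDGQ},
#'   \code{V_SDGQ}, \code{Z}, \code{p_value}, \code{adj_p}, \code{fdr}),
#'   the hit flags, the ranked list, and the call. Methods:
#'   \code{print}, \code{summary}, \code{plot}, \code{as.data.frame}.
#' @examples
#' sc <- simulation_scenario(n_genes = 500, n_qtls = 10, coverage = 0.3,
#'                           seed = 7)
#' gu <- simulate_genome(sc)
#' qs <- simulate_qtls(gu, sc)
#' d <- stats::setNames(abs(stats::rnorm(500)), gu$gene_id)
#' fit <- qtl_gse(gu, qs, d, sizes = c(50, 100, 200))
#' fit
#' @export
qtl_gse <- function(universe, qtls, scores,
                    sizes = seq(200L, 2000L, by = 100L),
                    mode = c("any", "containment"),
                    form = c("within_set", "literal"),
                    normalize_scores = FALSE, alpha = 0.05,
                    baselines = FALSE, B_perm = 2000L, B_sampling = 1000L,
                    seed = NULL) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  cl <- match.call()
  if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
  if (!inherits(qtls, "qtl_set")) qtls <- qtl_set(qtls)
  scores <- align_scores(scores, universe)
  if (normalize_scores && max(scores) > 0) scores <- scores / max(scores)

  flags <- qtl_hit_flags(universe, qtls, mode)
  N <- nrow(universe)
  V <- sum(flags)
  if (V == 0)
    stop("no gene in the universe is covered by any QTL; the competitive ",
         "null is degenerate and the test cannot be run")
  if (V == N)
    stop("every gene in the universe is covered by a QTL; the competitive ",
         "null is degenerate and the test cannot be run")
  if (any(sizes >= N))
    stop("gene-set sizes must be smaller than the universe size (", N, ")")

  ranked <- rank_genes(scores)
  sets <- threshold_gene_sets(ranked, sizes)
  if (!is.null(seed)) set.seed(seed)

  rows <- lapply(sets, function(G) {
    n <- length(G)
    idx <- match(G, universe$gene_id)
    v <- sum(flags[idx])
    nq <- nqhits(universe[idx, , drop = FALSE], qtls, mode)
    S <- sdgq(G, flags, scores, form)
    sm <- score_summary(scores[G])
    if (form == "within_set") {
      E <- e_sdgq(sm$EX, N, V, n)
      Vv <- v_sdgq(sm$EX, sm$VX, N, V, n)
    } else {
      pm <- perm_moments_literal(flags, scores, n, B = B_perm)
      E <- pm$E
      Vv <- pm$V
      if (Vv <= 0) stop("degenerate permutation variance for set size ", n)
    }
    z <- z_statistic(S, E, Vv)
    data.frame(size = n, NGQ = v, NQHits = nq, V = V, N = N, SDGQ = S,
               E_SDGQ = E, V_SDGQ = Vv, Z = z, p_value = z_pvalue(z))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$adj_p <- hochberg_adjust(res$p_value)
  res$fdr <- bh_fdr(res$p_value)

  if (baselines) {
    res$ora_p <- mapply(function(v, n) ora_hypergeom_test(v, N, V, n),
                        res$NGQ, res$size)
    res$sampling_p <- mapply(function(nq, n)
      gene_sampling_test(universe, qtls, n, nq, B = B_sampling)$p_value,
      res$NQHits, res$size)
  }

  structure(list(results = res, N = N, V = V, mode = mode, form = form,
                 alpha = alpha, normalize_scores = normalize_scores,
                 flags = flags, ranked = ranked, seed = seed, call = cl),
            class = "qtl_gse")
}

align_scores <- function(scores, universe) {
  if (is.data.frame(scores))
    scores <- stats::setNames(as.numeric(scores[[2]]), as.character(scores[[1]]))
  if (is.null(names(scores))) stop("scores must be named by gene id")
  check_score_vector(scores)
  unknown <- setdiff(names(scores), universe$gene_id)
  if (length(unknown))
    stop("score gene ids absent from the universe: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  missing <- setdiff(universe$gene_id, names(scores))
  if (length(missing))
    stop("universe gene ids missing from scores: ",
         paste(utils::head(missing, 10), collapse = ", "))
  scores[universe$gene_id]
}

#' @export
print.qtl_gse <- function(x, ...) {
  r <- x$results
  cat("Score-weighted QTL gene set enrichment test\n")
  cat(sprintf("  universe: N = %d genes, V = %d QTL-covered (%.1f%%)\n",
              x$N, x$V, 100 * x$V / x$N))
  cat(sprintf("  %d nested gene set(s), sizes %s; overlap mode '%s', form '%s'\n",
              nrow(r), paste(range(r$size), collapse = ".."), x$mode, x$form))
  nsig <- sum(r$adj_p <= x$alpha)
  cat(sprintf("  %d of %d set(s) enriched at Hochberg-adjusted p <= %.3g\n",
              nsig, nrow(r), x$alpha))
  invisible(x)
}

#' @export
summary.qtl_gse <- function(object, ...) {
  r <- object$results
  out <- list(results = r, alpha = object$alpha,
              n_significant = sum(r$adj_p <= object$alpha),
              best = r[which.min(r$p_value), , drop = FALSE],
              N = object$N, V = object$V)
  class(out) <- "summary.qtl_gse"
  out
}

#' @export
print.summary.qtl_gse <- function(x, digits = 4, ...) {
  cat(sprintf("QTL gene set enrichment over %d set(s); N = %d, V = %d\n\n",
              nrow(x$results), x$N, x$V))
  r <- x$results
  num <- vapply(r, is.numeric, logical(1))
  r[num] <- lapply(r[num], signif, digits = digits)
  print(r, row.names = FALSE)
  cat(sprintf("\n%d set(s) significant at Hochberg-adjusted p <= %.3g; ",
              x$n_significant, x$alpha))
  cat(sprintf("strongest enrichment at size %d (Z = %.3g, p = %.3g)\n",
              x$best$size, x$best$Z, x$best$p_value))
  invisible(x)
}

#' @export
as.data.frame.qtl_gse <- function(x, ...) x$results

#' Plot method: enrichment significance across gene-set sizes
#'
#' Plots \eqn{-\log_{10}} p-value against gene-set size, with the
#' Hochberg-adjusted values overlaid and the significance level marked.
#'
#' @param x a \code{qtl_gse} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.qtl_gse <- function(x, ...) {
  r <- x$results
  y <- -log10(pmax(r$p_value, .Machine$double.xmin))
  ya <- -log10(pmax(r$adj_p, .Machine$double.xmin))
  graphics::plot(r$size, y, type = "b", pch = 16,
                 xlab = "gene-set size", ylab = expression(-log[10](p)),
                 ylim = range(0, y, ya), ...)
  graphics::lines(r$size, ya, type = "b", pch = 1, lty = 2)
  graphics::abline(h = -log10(x$alpha), col = "grey50", lty = 3)
  graphics::legend("topright", bty = "n", pch = c(16, 1), lty = c(1, 2),
                   legend = c("raw p", "Hochberg adj. p"))
  invisible(x)
}
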