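#' Absolute two-sample t statistics as DE scores
#'
#' Per-gene differential expression scores for continuous (microarray-style)
#' expression values: the absolute value of the two-sample t statistic,
#' either Welch (default; unequal variances are the norm in expression data)
#' or pooled-variance.
#'
#' @param x numeric matrix, genes in rows, samples in columns; rownames are
#'   gene ids.
#' @param labels binary group membership per sample (1 = case, 0 = control),
#'   aligned to the columns of \code{x}.
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @return Named non-negative score vector aligned to the rows of \code{x}.
#'   Genes with zero variance in both groups score 0 (with a warning).
#' @export
t_scores <- function(x, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  labels <- check_labels(labels, ncol(x))
  i1 <- labels == 1L; i0 <- labels == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m0 <- rowMeans(x[, i0, drop = FALSE])
  v1 <- .row_vars(x[, i1, drop = FALSE], m1)
  v0 <- .row_vars(x[, i0, drop = FALSE], m0)
  se2 <- if (variant == "welch") {
    v1 / n1 + v0 / n0
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    sp2 * (1 / n1 + 1 / n0)
  }
  d <- abs(m1 - m0) / sqrt(se2)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero within-group variance in both ",
            "groups scored 0")
    d[degenerate] <- 0
  }
  names(d) <- rownames(x)
  d
}

.row_vars <- function(x, means) {
  if (ncol(x) < 2) stop("each group needs at least 2 samples")
  rowSums((x - means)^2) / (ncol(x) - 1)
}

check_labels <- function(labels, n_samples) {
  labels <- as.integer(labels)
  if (length(labels) != n_samples)
    stop("labels length (", length(labels), ") does not match sample count (",
         n_samples, ")")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both groups must be non-empty")
  labels
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalisation constants: each sample's median
#' ratio to the geometric-mean reference gene, computed over genes with a
#' positive count in every sample. Falls back to library size divided by the
#' mean library size when fewer than 10 such genes exist.
#'
#' @param counts non-negative count matrix, genes in rows.
#' @return Positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 10) {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    s <- apply(counts[pos, , drop = FALSE], 2,
               function(col) exp(stats::median(log(col) - logref)))
  } else {
    libs <- colSums(counts)
    if (any(libs <= 0)) stop("sample with zero total count")
    s <- libs / mean(libs)
  }
  s
}

#' Negative-binomial likelihood-ratio DE scores
#'
#' Per-gene scores for RNA-seq counts: the likelihood-ratio statistic
#' comparing an intercept-only negative-binomial GLM (log link, size-factor
#' offsets) against one with a binary group effect,
#' \eqn{D_i = 2(\ell_{alt} - \ell_{null}) \ge 0}. The NB variance is
#' \eqn{\mu + \phi\mu^2}; as \eqn{\phi \to 0} the model collapses to
#' Poisson. Dispersion is estimated per gene by a pooled within-group
#' method-of-moments estimator floored at 1e-8 (a deliberately simple,
#' pluggable estimator; precomputed scores can be supplied instead via
#' \code{\link{read_scores}}).
#'
#' With a binary covariate the alternative factorises into two independent
#' one-parameter fits, so each gene needs three concave one-dimensional
#' maximisations, done by vectorised Newton iteration on the log mean.
#'
#' @param counts non-negative integer matrix, genes in rows; rownames are
#'   gene ids.
#' @param labels binary group membership per sample (1/0).
#' @param sf size factors; default \code{\link{size_factors}(counts)}.
#' @param dispersion optional per-gene dispersion \eqn{\phi} (recycled);
#'   default method-of-moments.
#' @return Named non-negative score vector. All-zero genes score 0.
#' @export
nb_lrt_scores <- function(counts, labels, sf = NULL, dispersion = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  labels <- check_labels(labels, ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  phi <- if (is.null(dispersion)) mom_dispersion(counts, labels, sf)
         else pmax(rep_len(dispersion, nrow(counts)), 1e-8)
  theta <- 1 / phi
  ll0 <- nb_profile_loglik(counts, sf, theta)
  i1 <- labels == 1L
  ll1 <- nb_profile_loglik(counts[, i1, drop = FALSE], sf[i1], theta)
  ll2 <- nb_profile_loglik(counts[, !i1, drop = FALSE], sf[!i1], theta)
  d <- pmax(2 * (ll1 + ll2 - ll0), 0)
  names(d) <- rownames(counts)
  d
}

# Pooled within-group method-of-moments dispersion on size-factor-normalised
# counts: phi_g = (var - mean)/mean^2 per group, pooled by degrees of
# freedom, floored. Crude but adequate for rank + weighted-sum testing.
mom_dispersion <- function(counts, labels, sf, floor = 1e-8) {
  z <- sweep(counts, 2, sf, "/")
  num <- den <- numeric(nrow(counts))
  for (g in c(0L, 1L)) {
    zg <- z[, labels == g, drop = FALSE]
    df <- ncol(zg) - 1
    if (df < 1) next
    m <- rowMeans(zg)
    v <- rowSums((zg - m)^2) / df
    ok <- m > 0
    num[ok] <- num[ok] + df * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + df
  }
  phi <- ifelse(den > 0, num / pmax(den, 1), 0)
  pmax(phi, floor)
}

# Maximised NB log-likelihood per gene for the one-parameter model
# mu_gj = s_j * m_g with known theta_g: vectorised Newton on eta = log m.
# The log-likelihood is strictly concave in eta, so damped Newton converges.
nb_profile_loglik <- function(Y, s, theta) {
  G <- nrow(Y)
  ll <- numeric(G)
  tot <- rowSums(Y)
  live <- tot > 0
  if (any(live)) {
    Yl <- Y[live, , drop = FALSE]
    th <- theta[live]
    eta <- log(rowSums(Yl) / sum(s))
    for (iter in 1:50) {
      mu <- exp(eta) %o% s
      U <- rowSums(th * (Yl - mu) / (th + mu))
      I <- rowSums(th * mu * (th + Yl) / (th + mu)^2)
      step <- U / pmax(I, 1e-12)
      step <- pmin(pmax(step, -4), 4)
      eta <- eta + step
      if (max(abs(step)) < 1e-12) break
    }
    mu <- exp(eta) %o% s
    ll[live] <- rowSums(stats::dnbinom(Yl, size = th, mu = mu, log = TRUE))
  }
  # all-zero genes: sup of the likelihood is at mu -> 0 where P[Y=0] -> 1
  ll
}

#' Rank genes by decreasing DE score
#'
#' Stable descending sort with deterministic lexicographic (C locale)
#' tie-breaking on gene id, so nested gene-set membership never depends on
#' input order.
#'
#' @param scores named non-negative score vector (names are gene ids), or a
#'   two-column data.frame \code{gene_id, score}.
#' @return data.frame with columns \code{gene_id}, \code{score}, ordered by
#'   decreasing score.
#' @export
rank_genes <- function(scores) {
  if (is.data.frame(scores)) {
    df <- data.frame(gene_id = as.character(scores[[1]]),
                     score = as.numeric(scores[[2]]))
  } else {
    if (is.null(names(scores))) stop("scores must be named by gene id")
    df <- data.frame(gene_id = names(scores), score = as.numeric(scores))
  }
  check_score_vector(stats::setNames(df$score, df$gene_id))
  ord <- order(df$score, df$gene_id, method = "radix",
               decreasing = c(TRUE, FALSE))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

check_score_vector <- function(d) {
  if (anyNA(d) || any(!is.finite(d)))
    stop("DE scores must be finite and non-missing")
  if (any(d < 0))
    stop("DE scores must be non-negative (use |t| or LRT statistics; ",
         "signed scores are not supported)")
  if (any(duplicated(names(d))))
    stop("duplicated gene ids in score vector")
  invisible(d)
}

#' Nested gene sets from a ranked list
#'
#' Thresholds on the ranked list are realised as gene-set sizes: the k-th
#' set is the top \code{sizes[k]} genes, so the sets are nested.
#'
#' @param ranked a ranked gene list from \code{\link{rank_genes}}.
#' @param sizes strictly increasing gene-set sizes; default 200, 300, ...,
#'   2000 (19 sets).
#' @return Named list of gene-id character vectors.
#' @export
threshold_gene_sets <- function(ranked, sizes = seq(200L, 2000L, by = 100L)) {
  if (any(diff(sizes) <= 0) || any(sizes < 1))
    stop("gene-set sizes must be positive and strictly increasing")
  too_big <- sizes[sizes > nrow(ranked)]
  if (length(too_big))
    stop("gene-set size(s) exceed the universe size (", nrow(ranked), "): ",
         paste(too_big, collapse = ", "))
  sets <- lapply(sizes, function(k) ranked$gene_id[seq_len(k)])
  names(sets) <- sizes
  sets
}
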