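#' Simulation scenario for synthetic genome, QTL and count data
#'
#' Bundles all parameters of the synthetic-data generator. Defaults emulate
#' a rice-like RNA-seq study: 12 chromosomes, 2,000 genes with lengths of
#' 0.5-5 kb separated by 0.2-3 kb gaps, 30 megabase-scale QTL intervals
#' covering about 20\% of genes, 12 samples per group, 10\% DE genes at a
#' 2-fold change, NB dispersion 0.1 and relative depths spanning 0.7-1.3.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_genes universe size N.
#' @param gene_length length-2 vector: uniform bounds (bp) for gene lengths.
#' @param gap_length uniform bounds (bp) for intergenic gaps.
#' @param n_qtls number of QTL intervals.
#' @param qtl_length uniform bounds (bp) for QTL lengths, or NULL to derive
#'   them from the target coverage.
#' @param coverage target fraction of genes covered by at least one QTL.
#' @param samples_per_group samples in each of the two groups (M/2).
#' @param de_fraction fraction pi of genes that are differentially
#'   expressed.
#' @param lfc absolute log2 fold change |beta1| of DE genes (sign random).
#' @param dispersion NB dispersion phi (variance mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param beta0_mean,beta0_sd normal distribution of baseline log2 means.
#' @param libsize_range uniform bounds for relative library depths s_j.
#' @param coupling probability rho that a DE gene lies inside a QTL region;
#'   NULL (default) means the realised coverage V/N, i.e. no DE-QTL
#'   association (the null).
#' @param seed integer master seed; each generator stage uses its own
#'   derived substream so changing one stage does not perturb the others.
#' @return A \code{sim_scenario} list.
#' @export
simulation_scenario <- function(n_chromosomes = 12L, n_genes = 2000L,
                                gene_length = c(500, 5000),
                                gap_length = c(200, 3000),
                                n_qtls = 30L, qtl_length = NULL,
                                coverage = 0.2,
                                samples_per_group = 12L,
                                de_fraction = 0.1, lfc = 1,
                                dispersion = 0.1,
                                beta0_mean = 5, beta0_sd = 2,
                                libsize_range = c(0.7, 1.3),
                                coupling = NULL, seed = 1L) {
  sc <- list(n_chromosomes = as.integer(n_chromosomes),
             n_genes = as.integer(n_genes),
             gene_length = gene_length, gap_length = gap_length,
             n_qtls = as.integer(n_qtls), qtl_length = qtl_length,
             coverage = coverage,
             samples_per_group = as.integer(samples_per_group),
             de_fraction = de_fraction, lfc = lfc,
             dispersion = dispersion,
             beta0_mean = beta0_mean, beta0_sd = beta0_sd,
             libsize_range = libsize_range,
             coupling = coupling, seed = as.integer(seed))
  stopifnot(sc$n_genes >= 2, sc$n_chromosomes >= 1,
            sc$coverage >= 0, sc$coverage <= 1,
            sc$de_fraction >= 0, sc$de_fraction <= 1,
            sc$dispersion >= 0, sc$samples_per_group >= 2,
            diff(sc$gene_length) >= 0, sc$gene_length[1] >= 1)
  class(sc) <- "sim_scenario"
  sc
}

# Derived substream seeds keep the stages independent; offsets are fixed
# labels, and the master seed stays well below 2^31.
stage_seed <- function(sc, stage) {
  offset <- c(genome = 101L, qtls = 202L, counts = 303L)[[stage]]
  (sc$seed %% 1000000L) * 1000L + offset
}

#' Simulate a gene universe laid out on chromosomes
#'
#' Genes are placed left to right per chromosome with uniformly sampled
#' lengths and intergenic gaps; deterministic given the scenario seed.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @return A \code{\link{gene_universe}}.
#' @export
simulate_genome <- function(scenario) {
  sc <- scenario
  set.seed(stage_seed(sc, "genome"))
  N <- sc$n_genes
  chrom_of <- sort(rep_len(seq_len(sc$n_chromosomes), N))
  len <- round(stats::runif(N, sc$gene_length[1], sc$gene_length[2]))
  gap <- round(stats::runif(N, sc$gap_length[1], sc$gap_length[2]))
  start <- integer(N); end <- integer(N)
  for (ch in unique(chrom_of)) {
    i <- which(chrom_of == ch)
    s <- cumsum(gap[i] + c(0, utils::head(len[i], -1))) + 1
    start[i] <- s
    end[i] <- s + len[i] - 1
  }
  gene_universe(data.frame(
    gene_id = sprintf("g%05d", seq_len(N)),
    chrom = paste0("chr", chrom_of),
    start = start, end = end))
}

#' Simulate QTL intervals at a target gene coverage
#'
#' QTL intervals are placed uniformly on the chromosomes; whole placements
#' are redrawn (up to 200 attempts) until the realised covered-gene
#' fraction V/N is within 10\% (relative) of the target, else the closest
#' attempt is kept with a warning. Coverage 0 returns an empty set;
#' coverage 1 returns one chromosome-spanning QTL per chromosome.
#'
#' @param universe a \code{\link{gene_universe}}.
#' @param scenario a \code{\link{simulation_scenario}}.
#' @return A \code{\link{qtl_set}} with attribute \code{realized_coverage}.
#' @export
simulate_qtls <- function(universe, scenario) {
  sc <- scenario
  set.seed(stage_seed(sc, "qtls"))
  N <- nrow(universe)
  chrom_len <- tapply(universe$end, universe$chrom, max)
  chroms <- names(chrom_len)
  if (sc$coverage == 0) {
    out <- qtl_set(data.frame(qtl_id = character(), trait = character(),
                              chrom = character(), start = integer(),
                              end = integer()))
    attr(out, "realized_coverage") <- 0
    return(out)
  }
  if (sc$coverage >= 1) {
    out <- qtl_set(data.frame(
      qtl_id = paste0("q_", chroms), trait = "synthetic",
      chrom = chroms, start = 1L, end = as.integer(chrom_len)))
    attr(out, "realized_coverage") <- 1
    return(out)
  }
  qlen <- sc$qtl_length
  if (is.null(qlen)) {
    genes_per_qtl <- sc$coverage * N / sc$n_qtls
    span <- mean(universe$end - universe$start + 1) +
      mean(c(sc$gap_length[1], sc$gap_length[2]))
    L <- genes_per_qtl * span
    qlen <- c(0.8, 1.2) * L
  }
  draw <- function() {
    ch <- sample(chroms, sc$n_qtls, replace = TRUE,
                 prob = as.numeric(chrom_len))
    L <- round(stats::runif(sc$n_qtls, qlen[1], qlen[2]))
    st <- pmax(1, round(stats::runif(sc$n_qtls, 1, pmax(1, chrom_len[ch] - L))))
    qtl_set(data.frame(qtl_id = sprintf("q%03d", seq_len(sc$n_qtls)),
                       trait = "synthetic", chrom = ch,
                       start = st, end = st + L - 1))
  }
  best <- NULL; best_gap <- Inf
  for (attempt in 1:200) {
    cand <- draw()
    cov <- count_qtl_covered(universe, cand) / N
    gap <- abs(cov - sc$coverage)
    if (gap < best_gap) { best <- cand; best_gap <- gap; best_cov <- cov }
    if (gap <= 0.1 * sc$coverage) break
  }
  if (best_gap > 0.1 * sc$coverage)
    warning(sprintf(
      "coverage targeting did not converge in 200 attempts: target %.3f, realized %.3f",
      sc$coverage, best_cov))
  attr(best, "realized_coverage") <- best_cov
  best
}

#' Simulate NB counts with known DE and DE-QTL coupling ground truth
#'
#' Counts follow \eqn{Y_{ij} \sim NB(\mu_{ij}, \phi)} with
#' \eqn{\mu_{ij} = s_j 2^{\beta_{0i} + \beta_{1i} X_j}} and variance
#' \eqn{\mu + \phi \mu^2}; \eqn{\phi = 0} gives Poisson counts. A fraction
#' pi of genes receives \eqn{|\beta_1|} = \code{lfc} with random sign; each
#' DE gene is placed on a QTL-covered gene with probability rho
#' (\code{coupling}), so rho equal to the realised coverage is the null of
#' no DE-QTL association.
#'
#' @param universe a \code{\link{gene_universe}}.
#' @param qtls a \code{\link{qtl_set}}.
#' @param scenario a \code{\link{simulation_scenario}}.
#' @return List with \code{counts} (genes x samples integer matrix),
#'   \code{labels} (0/1 per sample), \code{truth} (per-gene data.frame:
#'   \code{gene_id}, \code{is_de}, \code{beta0}, \code{beta1},
#'   \code{qtl_hit}) and \code{depths} (the true relative depths s_j).
#' @export
simulate_counts <- function(universe, qtls, scenario) {
  sc <- scenario
  set.seed(stage_seed(sc, "counts"))
  N <- nrow(universe)
  M <- 2L * sc$samples_per_group
  labels <- rep(c(1L, 0L), each = sc$samples_per_group)
  flags <- suppressWarnings(qtl_hit_flags(universe, qtls))
  rho <- if (is.null(sc$coupling)) mean(flags) else sc$coupling

  n_de <- round(sc$de_fraction * N)
  covered <- which(flags == 1L); uncovered <- which(flags == 0L)
  n_from_cov <- stats::rbinom(1, n_de, rho)
  n_from_cov <- min(n_from_cov, length(covered))
  n_from_unc <- min(n_de - n_from_cov, length(uncovered))
  de_idx <- c(if (n_from_cov) sample(covered, n_from_cov),
              if (n_from_unc) sample(uncovered, n_from_unc))

  beta0 <- stats::rnorm(N, sc$beta0_mean, sc$beta0_sd)
  beta1 <- numeric(N)
  beta1[de_idx] <- sc$lfc * sample(c(-1, 1), length(de_idx), replace = TRUE)
  s <- stats::runif(M, sc$libsize_range[1], sc$libsize_range[2])

  log2mu <- outer(beta0, rep(1, M)) + outer(beta1, as.numeric(labels))
  mu <- sweep(2^log2mu, 2, s, "*")
  y <- if (sc$dispersion > 0)
    stats::rnbinom(N * M, size = 1 / sc$dispersion, mu = mu)
  else
    stats::rpois(N * M, lambda = mu)
  counts <- matrix(y, nrow = N, ncol = M,
                   dimnames = list(universe$gene_id,
                                   sprintf("s%02d_%s", seq_len(M),
                                           ifelse(labels == 1, "case", "ctrl"))))
  truth <- data.frame(gene_id = universe$gene_id,
                      is_de = seq_len(N) %in% de_idx,
                      beta0 = beta0, beta1 = beta1,
                      qtl_hit = as.integer(flags))
  list(counts = counts, labels = labels, truth = truth, depths = s)
}

#' Summary statistics of sequencing library sizes
#'
#' Total reads, mean reads per library (raw and rounded to the nearest
#' integer) and the coefficient of variation (population standard
#' deviation over the mean, reported to 3 decimals).
#'
#' @param sizes positive library sizes (total reads per library).
#' @return List with \code{total}, \code{mean}, \code{mean_rounded},
#'   \code{cv} and \code{n_libraries}.
#' @export
library_summary <- function(sizes) {
  if (!length(sizes)) stop("no library sizes supplied")
  if (anyNA(sizes) || any(sizes <= 0)) stop("library sizes must be positive")
  m <- mean(sizes)
  cv <- sqrt(mean((sizes - m)^2)) / m
  list(total = sum(sizes), mean = m, mean_rounded = round(m),
       cv = round(cv, 3), n_libraries = length(sizes))
}

#' Packaged rice salinity-stress RNA-seq library description
#'
#' The 24 single-end libraries (12 salinity-treated, 12 control; leaf and
#' root tissue of two rice genotypes) with their total read counts and GC
#' content, keyed by SRA run id.
#'
#' @return data.frame with columns \code{sample_id}, \code{sra_id},
#'   \code{genotype}, \code{tissue}, \code{class_label}, \code{total_reads},
#'   \code{gc_percent}.
#' @export
rice_salinity_libraries <- function() {
  path <- system.file("extdata", "rice_salinity_libraries.tsv",
                      package = "qtlsea", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged rice stress expression dataset catalogue
#'
#' One row per stress dataset: platform, number of series, retained gene
#' count and sample split, plus (where recorded) the pre-filtering gene
#' total and the counts of control and irrelevant genes removed by the
#' preliminary fold-change/p-value gene selection.
#'
#' @return data.frame; unavailable filtering counts are NA.
#' @export
rice_dataset_catalog <- function() {
  path <- system.file("extdata", "rice_dataset_catalog.tsv",
                      package = "qtlsea", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Genes retained by preliminary gene selection
#'
#' The arithmetic of the preliminary filter: from the initial gene total,
#' control probes and irrelevant (non-responsive) genes are removed.
#'
#' @param n_initial genes before filtering.
#' @param n_control control probe-set genes removed.
#' @param n_irrelevant irrelevant genes removed.
#' @return The retained gene count.
#' @export
retained_gene_count <- function(n_initial, n_control, n_irrelevant) {
  stopifnot(n_initial >= 0, n_control >= 0, n_irrelevant >= 0)
  out <- n_initial - n_control - n_irrelevant
  if (out < 0) stop("filter removes more genes than exist")
  out
}
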