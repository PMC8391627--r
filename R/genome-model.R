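#' Construct a gene universe
#'
#' The gene universe is the ordered whole-genome gene list against which
#' competitive enrichment is assessed: every gene that entered the expression
#' study, with its genomic coordinates. Its size \eqn{N} is the population
#' size of the hypergeometric null.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}. Coordinates are 1-based and inclusive (GFF3
#'   convention); see \code{\link{read_gene_universe}} for BED conversion.
#' @return A \code{gene_universe} object (a validated data.frame).
#' @examples
#' gu <- gene_universe(data.frame(
#'   gene_id = c("g1", "g2"), chrom = "chr1",
#'   start = c(100, 1000), end = c(500, 1800)))
#' nrow(gu)
#' @export
gene_universe <- function(genes) {
  genes <- as.data.frame(genes)
  req <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("gene universe is missing column(s): ", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  .check_intervals(genes, "gene")
  if (any(!nzchar(genes$gene_id)))
    stop("empty gene_id in gene universe")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicated gene_id in gene universe: ",
         paste(utils::head(unique(dup), 10), collapse = ", "))
  if (nrow(genes) < 2)
    stop("gene universe must contain at least 2 genes")
  rownames(genes) <- NULL
  structure(genes[req], class = c("gene_universe", "data.frame"))
}

#' Construct a QTL region set
#'
#' @param qtls data.frame with columns \code{qtl_id}, \code{trait},
#'   \code{chrom}, \code{start}, \code{end}; 1-based inclusive coordinates.
#'   An empty set is allowed but downstream enrichment tests refuse it.
#' @return A \code{qtl_set} object (a validated data.frame).
#' @export
qtl_set <- function(qtls) {
  qtls <- as.data.frame(qtls)
  req <- c("qtl_id", "trait", "chrom", "start", "end")
  miss <- setdiff(req, names(qtls))
  if (length(miss))
    stop("QTL set is missing column(s): ", paste(miss, collapse = ", "))
  qtls$qtl_id <- as.character(qtls$qtl_id)
  qtls$trait <- as.character(qtls$trait)
  qtls$chrom <- as.character(qtls$chrom)
  if (nrow(qtls)) .check_intervals(qtls, "QTL")
  dup <- qtls$qtl_id[duplicated(qtls$qtl_id)]
  if (length(dup))
    stop("duplicated qtl_id: ", paste(utils::head(unique(dup), 10), collapse = ", "))
  rownames(qtls) <- NULL
  structure(qtls[req], class = c("qtl_set", "data.frame"))
}

.check_intervals <- function(df, what) {
  start <- df$start; end <- df$end
  if (!is.numeric(start) || !is.numeric(end) || anyNA(start) || anyNA(end))
    stop(what, " coordinates must be non-missing numbers")
  bad <- which(start < 1 | start > end)
  if (length(bad))
    stop(what, " interval(s) with start < 1 or start > stop at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(df)
}

# Chromosome labels compare as strings after trimming whitespace and
# case-folding a leading "chr" prefix, so "Chr1", "chr1" and "1" all match.
norm_chrom <- function(x) {
  x <- trimws(as.character(x))
  sub("^[Cc][Hh][Rr]", "", x)
}

#' QTL-hit indicator for a single gene/QTL pair
#'
#' A gene is hit by a QTL when both lie on the same chromosome and their
#' intervals overlap. Under \code{mode = "any"} sharing a single base pair
#' counts; under \code{mode = "containment"} the gene must lie entirely
#' inside the QTL interval. QTL intervals are typically megabase-scale, so
#' the two modes rarely disagree; \code{"any"} is the default.
#'
#' @param gene one-row data.frame (or list) with \code{chrom}, \code{start},
#'   \code{end}.
#' @param qtl one-row data.frame (or list) with \code{chrom}, \code{start},
#'   \code{end}.
#' @param mode \code{"any"} or \code{"containment"}.
#' @return 0 or 1.
#' @export
overlaps <- function(gene, qtl, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  if (!identical(norm_chrom(gene$chrom), norm_chrom(qtl$chrom))) return(0L)
  a <- gene$start; b <- gene$end; d <- qtl$start; e <- qtl$end
  hit <- if (mode == "any") max(a, d) <= min(b, e) else d <= a && b <= e
  as.integer(hit)
}

# Pairwise gene x QTL overlap counts: for each gene the number of QTLs it
# overlaps. Vectorised per chromosome; the workhorse behind hit flags,
# NQHits and V.
overlap_counts <- function(universe, qtls, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  n <- nrow(universe)
  counts <- integer(n)
  if (!nrow(qtls)) return(counts)
  gc <- norm_chrom(universe$chrom)
  qc <- norm_chrom(qtls$chrom)
  for (ch in unique(qc)) {
    gi <- which(gc == ch)
    if (!length(gi)) next
    qi <- which(qc == ch)
    a <- universe$start[gi]; b <- universe$end[gi]
    d <- qtls$start[qi]; e <- qtls$end[qi]
    hit <- if (mode == "any")
      outer(a, d, pmax) <= outer(b, e, pmin)
    else
      outer(a, d, ">=") & outer(b, e, "<=")
    counts[gi] <- as.integer(rowSums(hit))
  }
  counts
}

#' Per-gene QTL-hit flags over the universe
#'
#' @param universe a \code{\link{gene_universe}}.
#' @param qtls a \code{\link{qtl_set}}.
#' @param mode overlap mode, see \code{\link{overlaps}}.
#' @return Integer vector of 0/1 flags aligned to the universe, named by
#'   gene id. A gene overlapping several QTLs still gets flag 1. An empty
#'   QTL set yields all zeros with a warning.
#' @export
qtl_hit_flags <- function(universe, qtls, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  if (!nrow(qtls))
    warning("empty QTL set: all hit flags are zero; enrichment tests will refuse")
  counts <- overlap_counts(universe, qtls, mode)
  flags <- as.integer(counts > 0L)
  names(flags) <- universe$gene_id
  flags
}

#' Gene-by-QTL overlap pair count (NQHits)
#'
#' The double sum of the hit indicator over genes in a set and QTLs: a gene
#' overlapping k QTLs contributes k. Reported descriptively alongside the
#' distinct-gene hit count; the hypergeometric null applies to the latter.
#'
#' @param genes data.frame of gene annotations (rows of a universe).
#' @param qtls a \code{\link{qtl_set}}.
#' @param mode overlap mode.
#' @return Non-negative integer.
#' @export
nqhits <- function(genes, qtls, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  if (!nrow(genes)) stop("gene set is empty")
  sum(overlap_counts(genes, qtls, mode))
}

#' Number of QTL-covered genes in the universe (V)
#'
#' @inheritParams qtl_hit_flags
#' @return The count of distinct genes overlapping at least one QTL,
#'   \eqn{0 \le V \le N}.
#' @export
count_qtl_covered <- function(universe, qtls, mode = c("any", "containment")) {
  mode <- match.arg(mode)
  sum(overlap_counts(universe, qtls, mode) > 0L)
}
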