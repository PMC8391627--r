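# Small hand-checkable fixtures used across the suite.

# n genes of length 100 at starts 1, 201, 401, ... on one chromosome.
tiled_universe <- function(n, chrom = "chr1", gene_len = 100L, gap = 100L) {
  starts <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  gene_universe(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = chrom, start = starts, end = starts + gene_len - 1L))
}

# A QTL spanning genes first..last of a tiled universe (inclusive).
span_qtl <- function(universe, first, last, qtl_id = "q1", trait = "tr") {
  qtl_set(data.frame(qtl_id = qtl_id, trait = trait,
                     chrom = universe$chrom[first],
                     start = universe$start[first],
                     end = universe$end[last]))
}

# Universe with exactly V covered genes out of N: genes tiled on one
# chromosome, one QTL over the first V genes. Hit flags are deterministic.
covered_universe <- function(N, V) {
  gu <- tiled_universe(N)
  qs <- span_qtl(gu, 1L, V)
  list(universe = gu, qtls = qs)
}

random_scores <- function(universe) {
  stats::setNames(abs(stats::rnorm(nrow(universe))), universe$gene_id)
}
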