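#' Read a gene universe from BED or GFF3
#'
#' Parsing goes through \code{rtracklayer::import}, so BED's 0-based
#' half-open coordinates are converted to the package's 1-based inclusive
#' convention automatically. For GFF3 only \code{gene} features are kept
#' and the id is taken from the attribute named by \code{id_attr}.
#'
#' @param path BED (>= 4 columns, name field holding the gene id) or GFF3
#'   file.
#' @param format \code{"auto"} (by extension), \code{"bed"} or
#'   \code{"gff3"}.
#' @param id_attr GFF3 attribute key holding the gene id (default
#'   \code{"ID"}).
#' @return A \code{\link{gene_universe}}.
#' @export
read_gene_universe <- function(path, format = c("auto", "bed", "gff3"),
                               id_attr = "ID") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
              else stop("cannot infer format from '", path,
                        "'; pass format = \"bed\" or \"gff3\"")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = format))
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene", , drop = FALSE]
    ids <- gr[[id_attr]]
    if (is.null(ids) || anyNA(ids))
      stop("GFF3 gene feature(s) without a '", id_attr, "' attribute")
  } else {
    ids <- gr$name
    if (is.null(ids) || anyNA(ids))
      stop("BED file must carry gene ids in the name (4th) column")
  }
  df <- data.frame(gene_id = as.character(ids),
                   chrom = as.character(gr$seqnames),
                   start = gr$start, end = gr$end)
  message("read ", nrow(df), " gene(s) from ", path)
  gene_universe(df)
}

#' Read a QTL table
#'
#' Tab-separated with header \code{qtl_id trait chrom start stop};
#' coordinates 1-based inclusive. Lines starting with \code{#} are ignored.
#'
#' @param path TSV file path.
#' @return A \code{\link{qtl_set}}.
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expect_header(df, c("qtl_id", "trait", "chrom", "start", "stop"), path)
  check_numeric_col(df, "start", path)
  check_numeric_col(df, "stop", path)
  bad <- which(df$start > df$stop)
  if (length(bad))
    stop("QTL start > stop at data line(s): ", paste(utils::head(bad, 10),
         collapse = ", "), " of ", path)
  names(df)[names(df) == "stop"] <- "end"
  qtl_set(df)
}

#' Read a precomputed DE score vector
#'
#' Two-column TSV \code{gene_id score}; scores must be non-negative and
#' finite (use |t| or LRT statistics, not signed statistics).
#'
#' @param path TSV file path.
#' @return Named numeric score vector.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expect_header(df, c("gene_id", "score"), path)
  check_numeric_col(df, "score", path)
  d <- stats::setNames(as.numeric(df$score), as.character(df$gene_id))
  check_score_vector(d)
  d
}

#' Read an expression matrix
#'
#' TSV with the gene id in the first column and one column per sample
#' (header row of sample ids).
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 3)
    stop("expression matrix needs a gene_id column plus >= 2 samples: ", path)
  ids <- as.character(df[[1]])
  if (any(duplicated(ids)))
    stop("duplicated gene ids in ", path)
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) {
    badcol <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
    stop("non-numeric values in sample column '", badcol, "' of ", path)
  }
  rownames(m) <- ids
  m
}

#' Read binary group labels
#'
#' Two-column TSV \code{sample class} with class 0 (control) or 1 (case).
#'
#' @param path TSV file path.
#' @return Named integer 0/1 vector.
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expect_header(df, c("sample", "class"), path)
  if (!all(df$class %in% c(0, 1)))
    stop("class column must be 0/1 in ", path)
  stats::setNames(as.integer(df$class), as.character(df$sample))
}

expect_header <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path,
         " (expected header: ", paste(cols, collapse = "\t"), ")")
  invisible(df)
}

check_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
  if (length(bad))
    stop("malformed numeric value in column '", col, "' at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), " of ", path)
  df[[col]] <- v
  invisible(df)
}

#' Write a result table
#'
#' Tab-separated, floats at 6 significant digits, preceded by
#' \code{#}-prefixed metadata lines (package version and test
#' configuration) so a result file is self-describing. Byte-identical for
#' identical inputs.
#'
#' @param x a \code{\link{qtl_gse}} fit or its result data.frame.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_results <- function(x, path) {
  meta <- c(paste0("# qtlsea_version=",
                   as.character(utils::packageVersion("qtlsea"))))
  if (inherits(x, "qtl_gse")) {
    meta <- c(meta,
              sprintf("# N=%d V=%d mode=%s form=%s alpha=%g normalize_scores=%s",
                      x$N, x$V, x$mode, x$form, x$alpha, x$normalize_scores),
              if (!is.null(x$seed)) sprintf("# seed=%d", x$seed))
    x <- x$results
  }
  out <- x
  dbl <- vapply(out, function(v) is.double(v), logical(1))
  out[dbl] <- lapply(out[dbl], function(v) as.character(signif(v, 6)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{write_results}}
#'
#' @param path file path.
#' @return data.frame of the per-set results.
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
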