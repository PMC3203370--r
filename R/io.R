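# Tab-delimited readers/writers. All writers render numerics with >= 15
# significant digits through fmt_num() so reruns are byte-identical and
# round-trips preserve values to ~1e-15 relative.

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; every remaining cell must be numeric. Missing or non-numeric
#' cells are rejected (no imputation) with an error naming the offending
#' gene row and sample column.
#'
#' @param path path to a tab-delimited file.
#' @return an [expression_matrix()] in `genes_by_samples` orientation, row
#'   and column order preserved from the file.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop_mfgex("file not found: ", path, class = "mfgex_io_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop_mfgex("expression file needs a gene-id column plus >=1 sample: ",
               path, class = "mfgex_format_error")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_mfgex("non-numeric or missing value at gene '", gene_ids[bad[1, 1]],
               "', sample '", sample_ids[bad[1, 2]], "'",
               class = "mfgex_format_error")
  expression_matrix(num, gene_ids, sample_ids, "genes_by_samples")
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()] (any orientation; written as
#'   genes-by-samples).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  x <- normalize_orientation(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(x)), collapse = "\t"), con)
  vals <- expr_values(x)
  lines <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(gene_ids(x)[i], fmt_num(vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read phenotype labels and check them against an expression matrix
#'
#' The file is two tab-separated columns (sample identifier, group label),
#' no header. Labels must cover exactly the matrix's samples and define
#' exactly two groups; group order is first-appearance order in the file.
#'
#' @param path path to the phenotype TSV.
#' @param matrix the companion [expression_matrix()].
#' @return a [phenotype_labels()] object.
#' @export
read_phenotypes <- function(path, matrix) {
  if (!file.exists(path))
    stop_mfgex("file not found: ", path, class = "mfgex_io_error")
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) != 2)
    stop_mfgex("phenotype file must have exactly 2 columns",
               class = "mfgex_format_error")
  ids <- df[[1]]
  expected <- sample_ids(matrix)
  unknown <- setdiff(ids, expected)
  if (length(unknown) > 0)
    stop_mfgex("phenotype file lists samples absent from the matrix: ",
               paste(unknown, collapse = ", "), class = "mfgex_format_error")
  missing <- setdiff(expected, ids)
  if (length(missing) > 0)
    stop_mfgex("samples missing from phenotype file: ",
               paste(missing, collapse = ", "), class = "mfgex_format_error")
  phenotype_labels(ids, df[[2]])
}

#' Write phenotype labels to TSV
#' @param labels a [phenotype_labels()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(labels, path) {
  writeLines(paste(names(labels$assignments), labels$assignments, sep = "\t"),
             path)
  invisible(path)
}

#' Write a results table to TSV
#'
#' Generic tab-delimited writer for gene-selection tables, component scores
#' and similar data frames: header row, floating point values at full
#' precision.
#'
#' @param rows a data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(rows), collapse = "\t"), con)
  if (nrow(rows) > 0) {
    cols <- lapply(rows, function(col) {
      if (is.numeric(col) && !is.integer(col)) fmt_num(col)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path path to the TSV file.
#' @return a data frame with columns type-converted.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
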