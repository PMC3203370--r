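#' Expression matrix container
#'
#' A labelled numeric matrix of expression values. The canonical orientation
#' is `genes_by_samples` (rows = genes, columns = samples); the transposed
#' orientation `samples_by_genes` is accepted and can be normalized with
#' [normalize_orientation()]. Gene and sample identifiers must be unique and
#' all values finite.
#'
#' @param values numeric matrix.
#' @param gene_ids character vector of unique gene identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @return an `mfgex_expr` object (the matrix with dimnames and an
#'   `orientation` attribute).
#' @export
expression_matrix <- function(values, gene_ids, sample_ids,
                              orientation = c("genes_by_samples",
                                              "samples_by_genes")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids))
    stop_mfgex("duplicate gene identifiers: ",
               paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
               class = "mfgex_format_error")
  if (anyDuplicated(sample_ids))
    stop_mfgex("duplicate sample identifiers: ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
               class = "mfgex_format_error")
  expected <- if (orientation == "genes_by_samples")
    c(length(gene_ids), length(sample_ids))
  else c(length(sample_ids), length(gene_ids))
  if (!identical(dim(values), as.integer(expected)))
    stop_mfgex("matrix is ", nrow(values), "x", ncol(values),
               " but identifiers imply ", expected[1], "x", expected[2],
               class = "mfgex_format_error")
  if (!all(is.finite(values)))
    stop_mfgex("expression matrix contains non-finite values",
               class = "mfgex_format_error")
  dimnames(values) <- if (orientation == "genes_by_samples")
    list(gene_ids, sample_ids) else list(sample_ids, gene_ids)
  structure(values, orientation = orientation,
            class = c("mfgex_expr", "matrix", "array"))
}

#' @export
print.mfgex_expr <- function(x, ...) {
  cat(sprintf("<mfgex_expr> %d genes x %d samples (%s)\n",
              length(gene_ids(x)), length(sample_ids(x)),
              attr(x, "orientation")))
  invisible(x)
}

#' Accessors for expression-matrix identifiers
#' @param x an `mfgex_expr` object.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) {
  if (attr(x, "orientation") == "genes_by_samples") rownames(x) else colnames(x)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  if (attr(x, "orientation") == "genes_by_samples") colnames(x) else rownames(x)
}

#' Normalize an expression matrix to genes-by-samples orientation
#' @param x an `mfgex_expr` object.
#' @return the same data in `genes_by_samples` orientation.
#' @export
normalize_orientation <- function(x) {
  if (attr(x, "orientation") == "genes_by_samples") return(x)
  expression_matrix(t(unclass(x)), gene_ids(x), sample_ids(x),
                    "genes_by_samples")
}

# Plain genes x samples numeric matrix (no class), always normalized.
expr_values <- function(x) {
  x <- normalize_orientation(x)
  structure(unclass(x), orientation = NULL)
}

#' Phenotype labels for a two-group design
#'
#' Maps each sample to one of exactly two group labels. The group order is
#' first-appearance order; downstream the first group is treated as the
#' phenotype of interest (e.g. disease) when orienting components and calling
#' up/down regulation.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param groups character vector of group labels, parallel to `sample_ids`.
#' @return an `mfgex_phenotypes` object with elements `assignments` (named
#'   character vector sample -> group) and `groups` (ordered pair of labels).
#' @export
phenotype_labels <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups))
    stop_mfgex("sample_ids and groups differ in length",
               class = "mfgex_format_error")
  if (anyDuplicated(sample_ids))
    stop_mfgex("duplicate sample identifiers in phenotype labels",
               class = "mfgex_format_error")
  lv <- unique(groups)
  if (length(lv) != 2)
    stop_mfgex("expected exactly 2 phenotype groups, found ", length(lv),
               " (", paste(lv, collapse = ", "), ")",
               class = "mfgex_format_error")
  if (any(table(factor(groups, levels = lv)) < 2))
    stop_mfgex("each phenotype group needs at least 2 samples",
               class = "mfgex_format_error")
  assignments <- stats::setNames(groups, sample_ids)
  structure(list(assignments = assignments, groups = lv),
            class = "mfgex_phenotypes")
}

#' @export
print.mfgex_phenotypes <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = x$groups))
  cat(sprintf("<mfgex_phenotypes> %s\n",
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = " vs ")))
  invisible(x)
}

# Indices of samples belonging to each group, in the order of `ids`.
group_indices <- function(labels, ids) {
  grp <- labels$assignments[ids]
  lapply(labels$groups, function(g) which(grp == g))
}

#' Default 13-sample Alzheimer study design
#'
#' Five severe-disease samples followed by eight controls, matching the
#' hippocampal study design this pipeline emulates. The disease group comes
#' first and is the phenotype of interest.
#'
#' @param n_disease,n_control group sizes.
#' @return an [phenotype_labels()] object.
#' @export
default_phenotypes <- function(n_disease = 5, n_control = 8) {
  phenotype_labels(
    c(sprintf("AD_%d", seq_len(n_disease)),
      sprintf("ctrl_%d", seq_len(n_control))),
    c(rep("AD", n_disease), rep("control", n_control)))
}
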