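# Normalization into the two forms the factorizations require.

#' Standardize each sample to zero mean and unit standard deviation
#'
#' Each sample (column in genes-by-samples orientation) is centered and
#' scaled to standard deviation 1, computed with the n-1 denominator. This is
#' the normalization the ICA track consumes.
#'
#' @param matrix an [expression_matrix()].
#' @return a standardized [expression_matrix()] in genes-by-samples
#'   orientation.
#' @export
standardize_samples <- function(matrix) {
  vals <- expr_values(matrix)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop_mfgex("constant sample(s) cannot be standardized: ",
               paste(colnames(vals)[sds == 0], collapse = ", "),
               class = "mfgex_degenerate_error")
  out <- scale(vals, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  expression_matrix(out, gene_ids(matrix), sample_ids(matrix),
                    "genes_by_samples")
}

#' Shift gene rows so the matrix is nonnegative
#'
#' If the input is already nonnegative it is returned unchanged. Otherwise
#' every gene row containing a negative value is shifted by minus its row
#' minimum, flooring that row at exactly zero; rows already nonnegative are
#' left untouched. Within-gene differences are preserved exactly, which is
#' what metagene loadings summarize. This is the form the nsNMF track
#' consumes, built from the raw (unstandardized) matrix.
#'
#' @param matrix an [expression_matrix()].
#' @return a nonnegative [expression_matrix()].
#' @export
make_nonnegative <- function(matrix) {
  vals <- expr_values(matrix)
  mins <- apply(vals, 1, min)
  if (all(mins >= 0)) return(normalize_orientation(matrix))
  shift <- pmax(0, -mins)
  out <- vals + shift
  # guard against roundoff leaving a -0 or tiny negative
  out[out < 0] <- 0
  expression_matrix(out, gene_ids(matrix), sample_ids(matrix),
                    "genes_by_samples")
}
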