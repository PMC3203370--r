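# Turning factorization output into the headline products: component
# scoring, significant-gene tables, sample classification, factor-sorted
# biclusters, and the ICA/NMF overlap report.

# Welch two-sample t statistic, defined for degenerate inputs: 0 when both
# groups are constant and equal, signed Inf when constant and different.
welch_t <- function(x1, x2) {
  se2 <- stats::var(x1) / length(x1) + stats::var(x2) / length(x2)
  d <- mean(x1) - mean(x2)
  if (se2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(se2)
}

#' Score mixing-matrix columns for phenotype discrimination
#'
#' Formalizes the visual read of a Hinton diagram: for every component
#' (column of the mixing matrix), `sign_separation` is the best achievable
#' fraction of samples whose entry sign matches a group-constant sign
#' assignment (1.0 means the two groups are perfectly separated by sign),
#' and `t_statistic` is the Welch two-sample statistic between the groups'
#' entries. Components are ranked by `|t|`, ties broken by sign separation
#' then by lower index.
#'
#' @param mixing samples x components matrix; row names (or row order) must
#'   align with the labelled samples.
#' @param labels a [phenotype_labels()] object.
#' @return a data frame with columns `component`, `sign_separation`,
#'   `t_statistic`, `rank`.
#' @export
score_components <- function(mixing, labels) {
  mixing <- as.matrix(mixing)
  ids <- rownames(mixing)
  if (is.null(ids)) ids <- names(labels$assignments)
  if (!setequal(ids, names(labels$assignments)) ||
      nrow(mixing) != length(labels$assignments))
    stop_mfgex("mixing rows do not align with labelled samples",
               class = "mfgex_format_error")
  gi <- group_indices(labels, ids)
  if (any(lengths(gi) < 2))
    stop_mfgex("each phenotype group needs >= 2 samples",
               class = "mfgex_degenerate_error")
  m <- nrow(mixing)
  res <- lapply(seq_len(ncol(mixing)), function(j) {
    a <- mixing[, j]
    sep <- max(
      (sum(sign(a[gi[[1]]]) == 1) + sum(sign(a[gi[[2]]]) == -1)) / m,
      (sum(sign(a[gi[[1]]]) == -1) + sum(sign(a[gi[[2]]]) == 1)) / m)
    data.frame(component = j, sign_separation = sep,
               t_statistic = welch_t(a[gi[[1]]], a[gi[[2]]]))
  })
  out <- do.call(rbind, res)
  ord <- order(-abs(out$t_statistic), -out$sign_separation, out$component)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Components the pipeline treats as phenotype-discriminating
#'
#' All components with perfect sign separation; if none, the top-ranked
#' component alone.
#'
#' @param scores output of [score_components()].
#' @return integer vector of component indices.
#' @export
discriminating_components <- function(scores) {
  hit <- scores$component[scores$sign_separation == 1]
  if (length(hit) > 0) sort(hit) else scores$component[scores$rank == 1]
}

new_gene_table <- function(gene_id = character(), method = character(),
                           component = integer(), loading = numeric(),
                           zscore = numeric(), direction = character()) {
  data.frame(gene_id = gene_id, method = method, component = component,
             loading = loading, zscore = unname(zscore),
             direction = unname(direction), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Significant genes from ICA expression modes
#'
#' Each chosen source row is standardized to z-scores across genes (n-1
#' denominator) and genes with `|z| >= threshold` are emitted (boundary
#' inclusive). Before thresholding, the mode is oriented so that the
#' phenotype group of interest (the first group in label order) has a
#' positive mean mixing weight; `up` then means elevated in that group.
#' This anchoring absorbs ICA's sign indeterminacy.
#'
#' @param result an `mfgex_ica` fit.
#' @param labels a [phenotype_labels()] object.
#' @param components integer vector of component indices to mine.
#' @param threshold positive |z| cutoff (default 2.5).
#' @return a gene-selection data frame (`gene_id`, `method`, `component`,
#'   `loading`, `zscore`, `direction`).
#' @export
select_genes_ica <- function(result, labels, components, threshold = 2.5) {
  if (length(components) == 0)
    stop_mfgex("no components chosen", class = "mfgex_param_error")
  if (any(components < 1 | components > nrow(result$sources)))
    stop_mfgex("component index out of range", class = "mfgex_param_error")
  ids <- rownames(result$mixing)
  gi <- group_indices(labels, ids)
  tabs <- lapply(components, function(cc) {
    x <- result$sources[cc, ]
    if (mean(result$mixing[gi[[1]], cc]) < 0) x <- -x
    z <- (x - mean(x)) / stats::sd(x)
    sel <- which(abs(z) >= threshold)
    new_gene_table(gene_id = colnames(result$sources)[sel],
                   method = rep("ica", length(sel)),
                   component = rep(as.integer(cc), length(sel)),
                   loading = unname(x[sel]), zscore = unname(z[sel]),
                   direction = ifelse(z[sel] > 0, "up", "down"))
  })
  do.call(rbind, tabs)
}

#' Significant genes from nsNMF metagenes
#'
#' Loadings of each metagene (column of W) are standardized to z-scores
#' across genes; genes with `z >= z_threshold` are selected (one-sided — W
#' is nonnegative, only large loadings are informative). Direction is read
#' from the raw data: `up` if the gene's mean expression in the phenotype
#' group of interest (first group in label order) exceeds the other group's
#' mean, else `down` (ties resolve to `down`).
#'
#' @param result an `mfgex_nsnmf` fit; its W rows must align with the data's
#'   genes.
#' @param data the raw (pre-standardization) [expression_matrix()].
#' @param labels a [phenotype_labels()] object.
#' @param z_threshold positive z cutoff (default 2.5).
#' @return a gene-selection data frame.
#' @export
select_genes_nmf <- function(result, data, labels, z_threshold = 2.5) {
  W <- result$metagenes
  vals <- expr_values(data)
  if (!is.null(rownames(W)) && !identical(rownames(W), gene_ids(data)))
    stop_mfgex("metagene rows do not align with the data's genes",
               class = "mfgex_format_error")
  if (!setequal(sample_ids(data), names(labels$assignments)))
    stop_mfgex("labels do not cover the data's samples",
               class = "mfgex_format_error")
  gi <- group_indices(labels, sample_ids(data))
  m1 <- rowMeans(vals[, gi[[1]], drop = FALSE])
  m2 <- rowMeans(vals[, gi[[2]], drop = FALSE])
  up <- m1 > m2
  tabs <- lapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    z <- (w - mean(w)) / stats::sd(w)
    sel <- which(z >= z_threshold)
    new_gene_table(gene_id = gene_ids(data)[sel],
                   method = rep("nmf", length(sel)),
                   component = rep(j, length(sel)),
                   loading = unname(w[sel]), zscore = unname(z[sel]),
                   direction = ifelse(up[sel], "up", "down"))
  })
  do.call(rbind, tabs)
}

#' Classify samples from the encoding matrix
#'
#' Each sample is assigned to the most highly expressed metagene in that
#' sample: the argmax over the rows of its H column, ties resolving to the
#' lowest index. Class indices are 1-based.
#'
#' @param H nonnegative k x samples encoding matrix (or an `mfgex_nsnmf`
#'   fit, whose `encodings` are used).
#' @return integer vector of class indices, one per sample.
#' @export
classify_samples <- function(H) {
  if (inherits(H, "mfgex_nsnmf")) H <- H$encodings
  H <- as.matrix(H)
  if (any(H < 0))
    stop_mfgex("H must be nonnegative", class = "mfgex_param_error")
  stats::setNames(apply(H, 2, which.max), colnames(H))
}

#' Bicluster the data by sorting on one factor
#'
#' Orders genes by descending metagene loading `W[, factor]` and samples by
#' descending encoding weight `H[factor, ]`, ties kept in original order.
#' A pure reordering: no values change, so applying the returned orders to
#' the data collects the factor's local expression module at the top-left.
#'
#' @param data the [expression_matrix()] being sorted.
#' @param result an `mfgex_nsnmf` fit.
#' @param factor metagene index (1-based).
#' @return a list with `row_order` and `col_order` (1-based permutations)
#'   plus the reordered `gene_ids` and `sample_ids`.
#' @export
bicluster_sort <- function(data, result, factor) {
  k <- ncol(result$metagenes)
  if (factor < 1 || factor > k)
    stop_mfgex("factor must be in 1..", k, class = "mfgex_param_error")
  row_order <- order(-result$metagenes[, factor], method = "radix")
  col_order <- order(-result$encodings[factor, ], method = "radix")
  list(row_order = row_order, col_order = col_order,
       gene_ids = gene_ids(data)[row_order],
       sample_ids = sample_ids(data)[col_order])
}

# Collapse a gene's directions within one method: "up"/"down"/"mixed".
collapse_direction <- function(dirs) {
  u <- unique(dirs)
  if (length(u) == 1) u else "mixed"
}

#' Integrate the ICA and NMF significant-gene lists
#'
#' The two factorizations impose different constraints (statistical
#' independence vs nonnegativity with sparseness) and typically agree on
#' few genes; integrating their lists widens the candidate set. The report
#' gives both gene sets, their intersection, union and Jaccard index, and a
#' per-gene provenance table flagging direction conflicts between methods.
#'
#' @param ica_table,nmf_table gene-selection data frames from
#'   [select_genes_ica()] and [select_genes_nmf()].
#' @return an `mfgex_overlap` list: `ica_genes`, `nmf_genes`,
#'   `intersection`, `union`, `jaccard`, and `genes` (data frame with
#'   `gene_id`, `status` in ica_only/nmf_only/both, per-method directions,
#'   `conflict`).
#' @export
integrate_gene_sets <- function(ica_table, nmf_table) {
  ica_genes <- unique(ica_table$gene_id)
  nmf_genes <- unique(nmf_table$gene_id)
  inter <- intersect(ica_genes, nmf_genes)
  uni <- union(ica_genes, nmf_genes)
  jaccard <- if (length(uni) == 0) 0 else length(inter) / length(uni)
  dir_of <- function(tab, gene) {
    d <- tab$direction[tab$gene_id == gene]
    if (length(d) == 0) NA_character_ else collapse_direction(d)
  }
  genes <- data.frame(
    gene_id = uni,
    status = ifelse(uni %in% inter, "both",
                    ifelse(uni %in% ica_genes, "ica_only", "nmf_only")),
    ica_direction = vapply(uni, dir_of, character(1), tab = ica_table),
    nmf_direction = vapply(uni, dir_of, character(1), tab = nmf_table),
    stringsAsFactors = FALSE, row.names = NULL)
  genes$conflict <- genes$status == "both" &
    (genes$ica_direction != genes$nmf_direction |
       genes$ica_direction == "mixed" | genes$nmf_direction == "mixed")
  structure(list(ica_genes = ica_genes, nmf_genes = nmf_genes,
                 intersection = inter, union = uni, jaccard = jaccard,
                 genes = genes),
            class = "mfgex_overlap")
}

#' @export
print.mfgex_overlap <- function(x, ...) {
  cat(sprintf(
    "<mfgex_overlap> ica=%d, nmf=%d, both=%d, Jaccard=%.3f, conflicts=%d\n",
    length(x$ica_genes), length(x$nmf_genes), length(x$intersection),
    x$jaccard, sum(x$genes$conflict)))
  invisible(x)
}
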