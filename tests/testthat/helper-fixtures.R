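# Shared fixtures and oracle helpers; everything is generated in code.

tiny_labels <- function(n1 = 3, n2 = 4) {
  phenotype_labels(
    c(sprintf("d%d", seq_len(n1)), sprintf("c%d", seq_len(n2))),
    c(rep("disease", n1), rep("control", n2)))
}

# Best classification agreement over the two class-label permutations
# (NMF component order is arbitrary).
class_agreement <- function(classes, labels) {
  truth <- as.integer(factor(labels$assignments[names(classes)],
                             levels = labels$groups))
  max(sum(classes == truth), sum(classes == 3L - truth))
}

jaccard_sets <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

# Per selected metagene, the best Jaccard against any planted module.
module_jaccard <- function(gene_table, truth, k) {
  vapply(seq_len(k), function(j) {
    sel <- gene_table$gene_id[gene_table$component == j]
    max(vapply(truth$metagene_modules, jaccard_sets, numeric(1), b = sel))
  }, numeric(1))
}

# Independent FastICA reference (scikit-learn) on a samples x genes matrix;
# returns the estimated sources (components x genes). Oracle only.
sklearn_fastica_sources <- function(X, n_components = nrow(X)) {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(X, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(
    "import numpy as np\nfrom sklearn.decomposition import FastICA\nX = np.loadtxt(%s, delimiter=',')\nica = FastICA(n_components=%d, fun='logcosh', whiten='unit-variance', tol=1e-8, max_iter=2000, random_state=0)\nS = ica.fit_transform(X.T)\nnp.savetxt(%s, S.T, delimiter=',')\n",
    deparse(infile), n_components, deparse(outfile))
  status <- system2("python", c("-c", shQuote(script)), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0) stop("reference FastICA oracle failed to run")
  as.matrix(utils::read.table(outfile, sep = ","))
}

# Greedy |correlation| matching of estimated source rows to true rows;
# returns the matched |r| per true row.
matched_abs_cor <- function(true_sources, est_sources) {
  C <- abs(stats::cor(t(true_sources), t(est_sources)))
  out <- numeric(nrow(true_sources))
  for (i in seq_len(nrow(true_sources))) {
    pos <- arrayInd(which.max(C), dim(C))
    out[pos[1]] <- C[pos[1], pos[2]]
    C[pos[1], ] <- -1
    C[, pos[2]] <- -1
  }
  out
}
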