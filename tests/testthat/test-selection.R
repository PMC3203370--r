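make_labels_13 <- function() default_phenotypes()

test_that("a sign-separated column scores 1.0 and the Welch t matches t.test", {
  labels <- make_labels_13()
  col <- c(-1, -2, -1.5, -1, -2, 1, 1.5, 0.5, 1, 2, 1, 0.5, 1.5)
  mixing <- cbind(col, rnorm(13))
  rownames(mixing) <- names(labels$assignments)
  sc <- score_components(mixing, labels)
  expect_equal(sc$sign_separation[1], 1.0)
  expect_identical(sc$rank[1], 1L)
  ref <- t.test(col[1:5], col[6:13])$statistic
  expect_equal(sc$t_statistic[1], unname(ref), tolerance = 1e-12)
})

test_that("degenerate columns score t = 0 and rank last", {
  labels <- make_labels_13()
  mixing <- cbind(rep(2, 13), c(rnorm(5, -3), rnorm(8, 3)))
  rownames(mixing) <- names(labels$assignments)
  sc <- score_components(mixing, labels)
  expect_equal(sc$t_statistic[1], 0)
  expect_identical(sc$rank[1], 2L)
  # all-positive constant column: best sign assignment matches the larger group
  expect_equal(sc$sign_separation[1], 8 / 13)
})

test_that("scoring is invariant to sample reordering and column sign flips", {
  set.seed(90)
  labels <- make_labels_13()
  mixing <- matrix(rnorm(13 * 4), 13, 4,
                   dimnames = list(names(labels$assignments), NULL))
  base <- score_components(mixing, labels)
  perm <- sample(13)
  reordered <- score_components(mixing[perm, ], labels)
  expect_equal(reordered, base)
  flipped <- score_components(mixing %*% diag(c(-1, 1, -1, 1)), labels)
  expect_equal(flipped$t_statistic, base$t_statistic * c(-1, 1, -1, 1))
  expect_equal(flipped$rank, base$rank)
  expect_equal(flipped$sign_separation, base$sign_separation)
})

test_that("planted discrimination beats the permutation null", {
  labels <- make_labels_13()
  sim <- simulate_ica_dataset(n_genes = 50, labels = labels, n_modes = 4,
                              seed = 91L)
  # mixing as ICA would see it: planted matrix plus small estimation noise
  set.seed(91)
  mixing <- sim$truth$mixing_matrix + matrix(rnorm(13 * 4, sd = 0.1), 13)
  rownames(mixing) <- names(labels$assignments)
  observed_top <- max(abs(score_components(mixing, labels)$t_statistic))
  grp <- labels$assignments
  exceed <- 0L
  n_perm <- 500L
  for (i in seq_len(n_perm)) {
    shuffled <- phenotype_labels(names(grp), sample(unname(grp)))
    null_top <- max(abs(score_components(mixing, shuffled)$t_statistic))
    if (null_top >= observed_top) exceed <- exceed + 1L
  }
  expect_lt(exceed / n_perm, 0.05)
})

test_that("ICA gene selection is boundary-inclusive and phenotype-anchored", {
  labels <- tiny_labels(2, 2)
  set.seed(77)
  src <- c(3.0, -2.6, 0.1, 2.5, rnorm(96))  # spikes on a normal background
  ngenes <- length(src)
  fake <- structure(list(
    sources = matrix(src, 1, ngenes,
                     dimnames = list("IC1", sprintf("g%03d", 1:ngenes))),
    mixing = matrix(c(1, 1, -1, -1), 4, 1,
                    dimnames = list(names(labels$assignments), "IC1"))),
    class = "mfgex_ica")
  z <- (src - mean(src)) / sd(src)  # oracle for the internal standardization
  tab <- select_genes_ica(fake, labels, components = 1, threshold = 2.5)
  expect_identical(tab$gene_id, sprintf("g%03d", which(abs(z) >= 2.5)))
  expect_identical(tab$direction, ifelse(z[abs(z) >= 2.5] > 0, "up", "down"))

  # the threshold comparison is inclusive: a gene exactly at the cutoff stays
  at_boundary <- select_genes_ica(fake, labels, components = 1,
                                  threshold = max(abs(z)))
  expect_identical(nrow(at_boundary), 1L)

  # flipping the mode and its mixing column leaves the output unchanged
  flipped <- fake
  flipped$sources <- -fake$sources
  flipped$mixing <- -fake$mixing
  tab2 <- select_genes_ica(flipped, labels, components = 1, threshold = 2.5)
  expect_identical(tab2, tab)

  high <- select_genes_ica(fake, labels, components = 1, threshold = 99)
  expect_identical(nrow(high), 0L)
  expect_error(select_genes_ica(fake, labels, integer(0)), "no components")
})

test_that("ICA selection recovers planted significant genes", {
  labels <- make_labels_13()
  sim <- simulate_ica_dataset(n_genes = 1000, labels = labels, n_modes = 4,
                              frac_significant = 0.02, seed = 92L)
  std <- standardize_samples(sim$data)
  fit <- fastica_consensus(std, run_config(seed = 92L, ica_n_restarts = 10L))
  sc <- score_components(fit$mixing, labels)
  comps <- discriminating_components(sc)
  tab <- select_genes_ica(fit, labels, comps, threshold = 2.5)
  planted <- sim$truth$significant_gene_sets[[sim$truth$phenotype_mode_index]]
  truthset <- c(planted$up, planted$down)
  sens <- mean(truthset %in% tab$gene_id)
  fpr <- sum(!tab$gene_id %in% truthset) / (1000 - length(truthset))
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.02)
  # selected planted genes carry the planted direction tags exactly
  sel_planted <- tab[tab$gene_id %in% truthset, ]
  expect_identical(sel_planted$direction,
                   ifelse(sel_planted$gene_id %in% planted$up, "up", "down"))
})

test_that("NMF gene selection finds spikes, ties resolve down", {
  labels <- tiny_labels(2, 2)
  data <- expression_matrix(matrix(1, 100, 4), sprintf("g%03d", 1:100),
                            names(labels$assignments))
  W <- matrix(0.01, 100, 1)
  W[7, 1] <- 10
  fit <- structure(list(metagenes = W, encodings = matrix(1, 1, 4)),
                   class = "mfgex_nsnmf")
  tab <- select_genes_nmf(fit, data, labels, z_threshold = 2.5)
  expect_identical(tab$gene_id, "g007")
  expect_identical(tab$direction, "down")  # equal group means -> down
})

test_that("NMF selection recovers planted modules with matching direction", {
  labels <- make_labels_13()
  sim <- simulate_nmf_dataset(n_genes = 400, labels = labels, k = 2,
                              module_size = 40, seed = 93L)
  cfg <- run_config(seed = 93L, k = 2, nsnmf_n_restarts = 5L,
                    nsnmf_n_iter = 1000L)
  fit <- nsnmf_multistart(make_nonnegative(sim$data), cfg)
  tab <- select_genes_nmf(fit, sim$data, labels, z_threshold = 2.5)
  expect_true(all(module_jaccard(tab, sim$truth, 2) >= 0.8))
})

test_that("sample classification follows the argmax with lowest-index ties", {
  H <- cbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.7))
  colnames(H) <- c("a", "b", "c")
  expect_identical(classify_samples(H), c(a = 1L, b = 1L, c = 2L))
  expect_error(classify_samples(H - 1), "nonnegative")
})

test_that("planted-group encodings classify samples correctly", {
  labels <- make_labels_13()
  sim <- simulate_nmf_dataset(n_genes = 400, labels = labels, k = 2,
                              module_size = 40, seed = 94L)
  cfg <- run_config(seed = 94L, k = 2, nsnmf_n_restarts = 5L,
                    nsnmf_n_iter = 1000L)
  fit <- nsnmf_multistart(make_nonnegative(sim$data), cfg)
  expect_gte(class_agreement(classify_samples(fit), labels), 12L)
})

test_that("bicluster sorting is a stable pure reordering", {
  labels <- tiny_labels(2, 2)
  data <- expression_matrix(matrix(rnorm(12), 3, 4), paste0("g", 1:3),
                            names(labels$assignments))
  fit <- structure(list(metagenes = cbind(c(0.1, 0.9, 0.5)),
                        encodings = matrix(c(1, 3, 2, 3), 1, 4)),
                   class = "mfgex_nsnmf")
  bs <- bicluster_sort(data, fit, 1)
  expect_identical(bs$row_order, c(2L, 3L, 1L))
  expect_identical(bs$col_order, c(2L, 4L, 3L, 1L))  # tie 3 keeps file order
  expect_identical(sort(bs$row_order), 1:3)          # a permutation
  expect_error(bicluster_sort(data, fit, 2), "factor must be")

  # shuffling gene order yields the same sorted gene_id sequence
  set.seed(95)
  perm <- sample(3)
  shuffled <- expression_matrix(unclass(data)[perm, ],
                                gene_ids(data)[perm], sample_ids(data))
  fit_p <- fit
  fit_p$metagenes <- fit$metagenes[perm, , drop = FALSE]
  expect_identical(bicluster_sort(shuffled, fit_p, 1)$gene_ids, bs$gene_ids)
})

test_that("gene-set integration reports overlap, Jaccard and conflicts", {
  ica <- data.frame(gene_id = c("a", "b", "c"), method = "ica",
                    component = 1L, loading = 1, zscore = 3,
                    direction = c("up", "up", "down"))
  nmf <- data.frame(gene_id = c("b", "c", "d"), method = "nmf",
                    component = 1L, loading = 1, zscore = 3,
                    direction = c("up", "up", "down"))
  rep <- integrate_gene_sets(ica, nmf)
  expect_setequal(rep$intersection, c("b", "c"))
  expect_equal(rep$jaccard, 0.5)
  g <- rep$genes
  expect_identical(g$status[g$gene_id == "a"], "ica_only")
  expect_false(g$conflict[g$gene_id == "b"])   # up vs up
  expect_true(g$conflict[g$gene_id == "c"])    # down vs up

  disjoint <- integrate_gene_sets(ica, nmf[nmf$gene_id == "d", ])
  expect_equal(disjoint$jaccard, 0)
  expect_false(any(disjoint$genes$conflict))
})
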