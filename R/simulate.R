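# Synthetic expression data with planted ground truth. The generators
# emulate the 13-sample (5 disease + 8 control) x 6398-gene hippocampal
# design: planted statistically independent expression modes for the ICA
# track and sparse nonnegative metagene modules for the NMF track, with at
# least one planted structure tied to phenotype. Every dimension and effect
# size is a parameter; the defaults are the study conditions.

#' Simulate an expression matrix with planted independent expression modes
#'
#' Each planted mode is a sparse super-Gaussian signal: a standard-normal
#' background over genes with a `frac_significant` subset shifted to
#' magnitude `signal_z` (sign recorded as up/down). Those spikes double as
#' the "significant genes" downstream selection should recover. The data
#' matrix is `mixing %*% modes` plus Gaussian noise; the mixing column of
#' the phenotype mode has group-constant magnitude and opposite signs in the
#' two groups, so it perfectly sign-separates the groups before noise.
#'
#' @param n_genes number of genes.
#' @param labels a [phenotype_labels()] object; its sample count sets `m`.
#' @param n_modes number of planted modes (at most the number of samples).
#' @param frac_significant fraction of genes spiked per mode; spike sets are
#'   disjoint across modes.
#' @param signal_z spike magnitude in background standard deviations.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; generation is a pure function of it.
#' @return a list with `data` (an [expression_matrix()], genes x samples)
#'   and `truth` (planted `mode_matrix`, `mixing_matrix`,
#'   `significant_gene_sets` with up/down tags, `phenotype_mode_index`).
#' @export
simulate_ica_dataset <- function(n_genes = 6398, labels = default_phenotypes(),
                                 n_modes = 13, frac_significant = 0.02,
                                 signal_z = 4, noise_sd = 0.5, seed = 17L) {
  m <- length(labels$assignments)
  if (n_modes > m)
    stop_mfgex("n_modes (", n_modes, ") exceeds number of samples (", m, ")",
               class = "mfgex_param_error")
  n_sig <- max(1L, round(frac_significant * n_genes))
  if (n_modes * n_sig > n_genes)
    stop_mfgex("cannot plant ", n_modes, " disjoint sets of ", n_sig,
               " significant genes in ", n_genes, " genes",
               class = "mfgex_param_error")
  gids <- sprintf("g%05d", seq_len(n_genes))
  sids <- names(labels$assignments)
  with_seed(seed, {
    modes <- matrix(stats::rnorm(n_modes * n_genes), nrow = n_modes)
    sig_pool <- sample.int(n_genes, n_modes * n_sig)
    sig_sets <- vector("list", n_modes)
    for (i in seq_len(n_modes)) {
      idx <- sig_pool[((i - 1) * n_sig + 1):(i * n_sig)]
      signs <- sample(c(-1, 1), n_sig, replace = TRUE)
      modes[i, idx] <- signs * signal_z
      sig_sets[[i]] <- list(up = gids[idx[signs > 0]],
                            down = gids[idx[signs < 0]])
    }
    phen_mode <- sample.int(n_modes, 1)
    mixing <- matrix(stats::rnorm(m * n_modes), nrow = m)
    gi <- group_indices(labels, sids)
    mixing[gi[[1]], phen_mode] <- 1
    mixing[gi[[2]], phen_mode] <- -1
    x <- t(mixing %*% modes)
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(n_genes * m, sd = noise_sd),
                      nrow = n_genes)
    truth <- structure(
      list(mode_matrix = modes, mixing_matrix = mixing,
           significant_gene_sets = sig_sets,
           phenotype_mode_index = phen_mode),
      class = "mfgex_truth")
    list(data = expression_matrix(x, gids, sids, "genes_by_samples"),
         truth = truth)
  })
}

#' Simulate a nonnegative expression matrix with planted metagene modules
#'
#' Plants `k` disjoint gene modules of `module_size` genes: the true
#' metagene matrix W carries loading ~`load_high` inside a module against a
#' `load_low` background, and the true encoding matrix H gives each
#' phenotype group elevated weight on its own metagene (groups map to the
#' first two metagenes; any further metagenes get moderate weight in all
#' samples). The emitted matrix is `W %*% H` plus zero-truncated Gaussian
#' noise, so it is nonnegative by construction.
#'
#' @param n_genes number of genes.
#' @param labels a [phenotype_labels()] object.
#' @param k number of planted metagenes.
#' @param module_size genes per module; `k * module_size <= n_genes`.
#' @param load_high,load_low module and background loading scales.
#' @param noise_sd standard deviation of the Gaussian noise before
#'   truncation at zero.
#' @param seed integer seed; generation is a pure function of it.
#' @return a list with `data` (nonnegative [expression_matrix()]) and
#'   `truth` (`metagene_matrix`, `encoding_matrix`, `metagene_modules` as
#'   gene-id sets, `group_metagene` mapping group label -> metagene index).
#' @export
simulate_nmf_dataset <- function(n_genes = 6398, labels = default_phenotypes(),
                                 k = 2, module_size = 500, load_high = 5,
                                 load_low = 0.25, noise_sd = 0.5, seed = 17L) {
  m <- length(labels$assignments)
  if (k * module_size > n_genes)
    stop_mfgex("k * module_size (", k * module_size, ") exceeds n_genes (",
               n_genes, "): disjoint modules impossible",
               class = "mfgex_param_error")
  gids <- sprintf("g%05d", seq_len(n_genes))
  sids <- names(labels$assignments)
  with_seed(seed, {
    W <- matrix(stats::runif(n_genes * k, 0, load_low), nrow = n_genes)
    pool <- sample.int(n_genes, k * module_size)
    modules <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- pool[((j - 1) * module_size + 1):(j * module_size)]
      W[idx, j] <- load_high * stats::runif(module_size, 0.9, 1.1)
      modules[[j]] <- gids[idx]
    }
    H <- matrix(stats::runif(k * m, 0.2, 0.5), nrow = k)
    gi <- group_indices(labels, sids)
    group_metagene <- stats::setNames(pmin(seq_along(gi), k), labels$groups)
    for (g in seq_along(gi)) {
      mg <- group_metagene[[g]]
      if (g > 1 && mg %in% group_metagene[seq_len(g - 1)]) next  # k == 1
      H[mg, gi[[g]]] <- stats::runif(length(gi[[g]]), 0.9, 1.1)
      H[mg, -gi[[g]]] <- stats::runif(m - length(gi[[g]]), 0.05, 0.15)
    }
    v <- W %*% H
    if (noise_sd > 0)
      v <- v + pmax(matrix(stats::rnorm(n_genes * m, sd = noise_sd),
                           nrow = n_genes), 0)
    truth <- structure(
      list(metagene_matrix = W, encoding_matrix = H,
           metagene_modules = modules, group_metagene = group_metagene),
      class = "mfgex_truth")
    list(data = expression_matrix(v, gids, sids, "genes_by_samples"),
         truth = truth)
  })
}

#' Write a planted-truth record to JSON
#'
#' @param truth the `truth` element returned by a simulator.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
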