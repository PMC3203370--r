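# End-to-end orchestration: simulate/load -> preprocess -> ICA -> nsNMF ->
# select -> integrate, with every intermediate written to disk and a
# manifest recording config, seeds and checksums. Stages communicate only
# through files, so a rerun with the same config and inputs is bitwise
# reproducible.

log_stage <- function(verbose, stage, msg) {
  if (verbose)
    message(sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

# data.frame with an id column from a labelled matrix (rows become ids).
matrix_to_df <- function(M, id_name) {
  df <- data.frame(rownames(M), as.data.frame(unclass(M)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  df
}

#' Run the full two-track pipeline
#'
#' Executes load, preprocess (sample standardization for the ICA track,
#' per-gene nonnegative shift for the NMF track), consensus FastICA, nsNMF
#' multistart, component scoring and gene selection on both tracks, sample
#' classification, factor-sorted bicluster orders, and gene-list
#' integration. Every intermediate artifact is written to `out_dir` and a
#' `manifest.json` records the configuration, completed stages, selected
#' components and an md5 checksum per output file. A rerun with the same
#' config and inputs reproduces all outputs bitwise.
#'
#' @param config a [run_config()].
#' @param expr_path path to the expression TSV (genes x samples).
#' @param pheno_path path to the phenotype TSV.
#' @param out_dir output directory (created if needed).
#' @param verbose log progress to the console.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config, expr_path, pheno_path, out_dir, verbose = TRUE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  completed <- character()
  run_stage <- function(stage, expr) {
    log_stage(verbose, stage, "starting")
    out <- tryCatch(expr, error = function(e) {
      stop_mfgex("stage '", stage, "' failed: ", conditionMessage(e),
                 class = "mfgex_stage_error")
    })
    completed <<- c(completed, stage)
    out
  }
  p <- function(name) file.path(out_dir, name)

  loaded <- run_stage("load", {
    data <- read_expression_matrix(expr_path)
    labels <- read_phenotypes(pheno_path, data)
    list(data = data, labels = labels)
  })
  prep <- run_stage("preprocess", {
    std <- standardize_samples(loaded$data)
    nn <- make_nonnegative(loaded$data)
    write_expression_matrix(std, p("standardized.tsv"))
    write_expression_matrix(nn, p("nonnegative.tsv"))
    list(std = std, nn = nn)
  })
  ica <- run_stage("ica", {
    fit <- fastica_consensus(prep$std, config)
    write_table(matrix_to_df(fit$mixing, "sample_id"), p("ica_mixing.tsv"))
    write_table(matrix_to_df(fit$sources, "component"), p("ica_sources.tsv"))
    write_table(data.frame(component = sprintf("IC%d",
                                               seq_along(fit$stability)),
                           stability = fit$stability,
                           negentropy = fit$objective),
                p("ica_stability.tsv"))
    fit
  })
  nmf <- run_stage("nsnmf", {
    fit <- nsnmf_multistart(prep$nn, config)
    write_table(matrix_to_df(fit$metagenes, "gene_id"), p("nmf_W.tsv"))
    write_table(matrix_to_df(fit$encodings, "metagene"), p("nmf_H.tsv"))
    write_table(data.frame(iteration = seq_along(fit$objective_trace),
                           kl_objective = fit$objective_trace),
                p("nmf_objective_trace.tsv"))
    jsonlite::write_json(
      list(restart_objectives = fit$restart_objectives,
           best_restart = fit$restart_id, theta = fit$theta,
           sparseness = unname(fit$sparseness)),
      p("nmf_diagnostics.json"), auto_unbox = TRUE, digits = NA)
    fit
  })
  sel <- run_stage("select", {
    scores <- score_components(ica$mixing, loaded$labels)
    comps <- discriminating_components(scores)
    ica_tab <- select_genes_ica(ica, loaded$labels, comps,
                                threshold = config$loading_threshold)
    nmf_tab <- select_genes_nmf(nmf, loaded$data, loaded$labels,
                                z_threshold = config$nmf_gene_z_threshold)
    classes <- classify_samples(nmf)
    write_table(scores, p("component_scores.tsv"))
    write_table(ica_tab, p("genes_ica.tsv"))
    write_table(nmf_tab, p("genes_nmf.tsv"))
    write_table(data.frame(sample_id = names(classes),
                           class = as.integer(classes)),
                p("sample_classes.tsv"))
    orders <- do.call(rbind, lapply(seq_len(config$k), function(f) {
      bs <- bicluster_sort(loaded$data, nmf, f)
      rbind(data.frame(factor = f, axis = "gene",
                       position = seq_along(bs$row_order),
                       index = bs$row_order, id = bs$gene_ids),
            data.frame(factor = f, axis = "sample",
                       position = seq_along(bs$col_order),
                       index = bs$col_order, id = bs$sample_ids))
    }))
    write_table(orders, p("bicluster_orders.tsv"))
    list(scores = scores, components = comps, ica_tab = ica_tab,
         nmf_tab = nmf_tab, classes = classes)
  })
  overlap <- run_stage("integrate", {
    rep <- integrate_gene_sets(sel$ica_tab, sel$nmf_tab)
    jsonlite::write_json(
      list(ica_genes = rep$ica_genes, nmf_genes = rep$nmf_genes,
           intersection = rep$intersection, union = rep$union,
           jaccard = rep$jaccard, genes = rep$genes),
      p("overlap.json"), auto_unbox = TRUE, digits = NA)
    rep
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(config = unclass(config), stages = completed,
                   selected_ica_components = sel$components,
                   n_ica_genes = length(unique(sel$ica_tab$gene_id)),
                   n_nmf_genes = length(unique(sel$nmf_tab$gene_id)),
                   overlap_jaccard = overlap$jaccard,
                   checksums = checksums)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage(verbose, "done", sprintf("%d stages, outputs in %s",
                                     length(completed), out_dir))
  invisible(manifest)
}
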