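#' Pipeline run configuration
#'
#' Bundles every tunable of the two factorization tracks with validated
#' defaults. The defaults are the study settings this pipeline emulates:
#' FastICA with the tanh contrast (`a1 = 1`) consolidated over 100 random
#' restarts, nsNMF at rank `k = 2` run 40 times for 2000 iterations, and a
#' significant-gene loading threshold of 2.5 on z-standardized loadings for
#' both tracks.
#'
#' @param seed integer run seed; every source of randomness derives from it.
#' @param a1 positive slope of the tanh contrast `g(u) = tanh(a1 * u)`.
#' @param ica_n_restarts number of FastICA random restarts to consolidate.
#' @param ica_tol convergence tolerance on the fixed-point iteration.
#' @param ica_max_iter iteration cap per restart.
#' @param loading_threshold |z| cutoff for significant genes on ICA modes.
#' @param k nsNMF rank (number of metagenes).
#' @param theta smoothing parameter in `[0, 1]`; 0 disables smoothing, values
#'   toward 1 force sparser factors.
#' @param nsnmf_n_restarts number of nsNMF random restarts.
#' @param nsnmf_n_iter multiplicative-update iterations per restart.
#' @param epsilon_floor positive floor applied to W and H entries so
#'   multiplicative updates cannot absorb exact zeros.
#' @param conv_tol optional relative objective-change early stop for nsNMF;
#'   0 disables it and the full iteration budget is used.
#' @param nmf_gene_z_threshold one-sided z cutoff for significant genes on
#'   metagene loadings.
#' @return a validated `mfgex_config` list.
#' @export
run_config <- function(seed = 17L,
                       a1 = 1.0,
                       ica_n_restarts = 100L,
                       ica_tol = 1e-6,
                       ica_max_iter = 1000L,
                       loading_threshold = 2.5,
                       k = 2L,
                       theta = 0.5,
                       nsnmf_n_restarts = 40L,
                       nsnmf_n_iter = 2000L,
                       epsilon_floor = 1e-9,
                       conv_tol = 0,
                       nmf_gene_z_threshold = 2.5) {
  cfg <- list(seed = as.integer(seed), a1 = a1,
              ica_n_restarts = as.integer(ica_n_restarts), ica_tol = ica_tol,
              ica_max_iter = as.integer(ica_max_iter),
              loading_threshold = loading_threshold,
              k = as.integer(k), theta = theta,
              nsnmf_n_restarts = as.integer(nsnmf_n_restarts),
              nsnmf_n_iter = as.integer(nsnmf_n_iter),
              epsilon_floor = epsilon_floor, conv_tol = conv_tol,
              nmf_gene_z_threshold = nmf_gene_z_threshold)
  validate_config(cfg)
  structure(cfg, class = "mfgex_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok)
    stop_mfgex("invalid configuration: ", msg, class = "mfgex_config_error")
  chk(is.finite(cfg$theta) && cfg$theta >= 0 && cfg$theta <= 1,
      "theta must lie in [0, 1]")
  chk(cfg$k >= 1, "k must be >= 1")
  chk(cfg$a1 > 0, "a1 must be positive")
  chk(cfg$ica_tol > 0, "ica_tol must be positive")
  chk(cfg$loading_threshold > 0, "loading_threshold must be positive")
  chk(cfg$nmf_gene_z_threshold > 0, "nmf_gene_z_threshold must be positive")
  chk(cfg$epsilon_floor > 0, "epsilon_floor must be positive")
  chk(cfg$conv_tol >= 0, "conv_tol must be >= 0")
  for (f in c("ica_n_restarts", "ica_max_iter", "nsnmf_n_restarts",
              "nsnmf_n_iter"))
    chk(cfg[[f]] >= 1, paste(f, "must be a positive count"))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Every field of [run_config()] may appear; omitted fields take their
#' defaults. Unknown fields are an error so typos do not silently fall back
#' to defaults.
#'
#' @param path path to a YAML file.
#' @return an `mfgex_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_mfgex("config file not found: ", path, class = "mfgex_io_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop_mfgex("unknown config fields: ", paste(unknown, collapse = ", "),
               class = "mfgex_config_error")
  do.call(run_config, raw)
}

#' @export
print.mfgex_config <- function(x, ...) {
  cat("<mfgex_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
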