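# Non-smooth NMF: smoothing matrix, multiplicative KL updates with the
# WS/SH substitution (C++ core), multi-restart model selection, and the
# Hoyer sparseness measure.

#' Build the nsNMF smoothing matrix
#'
#' `S = (1 - theta) * I + (theta / k) * 11^T`. At `theta = 0` this is the
#' identity (no smoothing, classical NMF); as `theta -> 1`, `S x` tends to
#' the constant mean vector of `x` — the smoothest possible vector — which
#' is what forces sparseness onto the factors on either side. S is
#' symmetric, nonnegative, and every row sums to 1.
#'
#' @param k factorization rank.
#' @param theta smoothing parameter in `[0, 1]`.
#' @return a `k x k` matrix with attributes `theta` and `k`.
#' @export
smoothing_matrix <- function(k, theta) {
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop_mfgex("theta must lie in [0, 1], got ", theta,
               class = "mfgex_param_error")
  if (k < 1)
    stop_mfgex("k must be >= 1", class = "mfgex_param_error")
  S <- (1 - theta) * diag(k) + (theta / k) * matrix(1, k, k)
  attr(S, "theta") <- theta
  attr(S, "k") <- as.integer(k)
  S
}

#' Hoyer sparseness of a nonnegative vector
#'
#' `(sqrt(d) - ||v||_1 / ||v||_2) / (sqrt(d) - 1)` for a length-`d` vector:
#' 0 for a constant vector, 1 for a one-hot vector. Scale-free.
#'
#' @param v nonnegative numeric vector, length >= 2, not all zero.
#' @return a value in `[0, 1]`.
#' @export
hoyer_sparseness <- function(v) {
  if (length(v) < 2)
    stop_mfgex("sparseness undefined for vectors of length < 2",
               class = "mfgex_param_error")
  if (any(v < 0))
    stop_mfgex("sparseness requires a nonnegative vector",
               class = "mfgex_param_error")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0)
    stop_mfgex("sparseness undefined for the zero vector",
               class = "mfgex_param_error")
  d <- length(v)
  (sqrt(d) - sum(v) / l2) / (sqrt(d) - 1)
}

#' One nsNMF run
#'
#' Factorizes a nonnegative genes-by-samples matrix `V` as `W S H` with the
#' divergence-form multiplicative updates, substituting `W S` for `W` in the
#' H-update and `S H` for `H` in the W-update. `W` and `H` start from a
#' seeded uniform draw on `(epsilon_floor, 1]` and every entry is floored at
#' `epsilon_floor` after each update so multiplicative updates cannot absorb
#' exact zeros. The generalized KL divergence `D(V || W S H)` is recorded
#' each iteration and is nonincreasing. After the final iteration the
#' columns of `W` are rescaled to unit l1 norm with the inverse scale
#' absorbed into `H`, making loadings comparable across metagenes (the
#' rescale is deferred to the end because it does not commute with the
#' smoothing matrix and would break the descent guarantee mid-run).
#'
#' @param V nonnegative [expression_matrix()] or plain genes x samples
#'   matrix.
#' @param k rank; `k <= min(dim(V))`.
#' @param theta smoothing parameter in `[0, 1]`.
#' @param n_iter iteration budget.
#' @param epsilon_floor positive floor for W and H entries.
#' @param seed integer seed for the initialization.
#' @param conv_tol optional relative objective-change early stop (0 = off).
#' @return an `mfgex_nsnmf` object: `metagenes` (W, genes x k, unit column
#'   sums), `encodings` (H, k x samples), `theta`, `objective_trace`,
#'   `final_objective`, `iterations`, `sparseness` (Hoyer, per W column),
#'   `restart_id`, `seed`.
#' @export
nsnmf_once <- function(V, k = 2, theta = 0.5, n_iter = 2000L,
                       epsilon_floor = 1e-9, seed = 1L, conv_tol = 0) {
  gids <- NULL; sids <- NULL
  if (inherits(V, "mfgex_expr")) {
    gids <- gene_ids(V); sids <- sample_ids(V)
    V <- expr_values(V)
  } else V <- as.matrix(V)
  if (any(V < 0))
    stop_mfgex("V must be nonnegative", class = "mfgex_param_error")
  n <- nrow(V); m <- ncol(V)
  if (k > min(n, m))
    stop_mfgex("k (", k, ") exceeds min(dim(V)) = ", min(n, m),
               class = "mfgex_param_error")
  if (any(rowSums(V) == 0) || any(colSums(V) == 0))
    warning("V has all-zero row(s) or column(s); their factors stay at the floor")
  S <- smoothing_matrix(k, theta)
  init <- with_seed(seed, list(
    W = matrix(stats::runif(n * k, min = epsilon_floor, max = 1), nrow = n),
    H = matrix(stats::runif(k * m, min = epsilon_floor, max = 1), nrow = k)))
  fit <- .nsnmf_core(V, init$W, init$H, S, as.integer(n_iter), epsilon_floor,
                     conv_tol)
  W <- fit$W; H <- fit$H
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  W[W < epsilon_floor] <- epsilon_floor
  H[H < epsilon_floor] <- epsilon_floor
  if (!is.null(gids)) rownames(W) <- gids
  colnames(W) <- sprintf("metagene%d", seq_len(k))
  rownames(H) <- colnames(W)
  if (!is.null(sids)) colnames(H) <- sids
  structure(list(metagenes = W, encodings = H, theta = theta,
                 objective_trace = fit$objective_trace,
                 final_objective = fit$objective_trace[fit$iterations],
                 iterations = fit$iterations,
                 sparseness = apply(W, 2, hoyer_sparseness),
                 restart_id = NA_integer_, seed = seed),
            class = "mfgex_nsnmf")
}

#' Multi-restart nsNMF
#'
#' Runs [nsnmf_once()] from `nsnmf_n_restarts` seeded initializations and
#' returns the restart with the lowest final KL objective; all final
#' objectives are kept for diagnostics.
#'
#' @param V nonnegative [expression_matrix()] or plain matrix.
#' @param config a [run_config()].
#' @return the best `mfgex_nsnmf` fit, with `restart_id` set and an extra
#'   `restart_objectives` vector.
#' @export
nsnmf_multistart <- function(V, config = run_config()) {
  fits_obj <- numeric(config$nsnmf_n_restarts)
  best <- NULL
  for (r in seq_len(config$nsnmf_n_restarts)) {
    fit <- nsnmf_once(V, k = config$k, theta = config$theta,
                      n_iter = config$nsnmf_n_iter,
                      epsilon_floor = config$epsilon_floor,
                      seed = derive_seed(config$seed, "nsnmf", r),
                      conv_tol = config$conv_tol)
    fit$restart_id <- r
    fits_obj[r] <- fit$final_objective
    if (is.null(best) || fit$final_objective < best$final_objective)
      best <- fit
  }
  best$restart_objectives <- fits_obj
  best
}

#' @export
print.mfgex_nsnmf <- function(x, ...) {
  cat(sprintf(
    "<mfgex_nsnmf> k=%d, theta=%.2f, %d iterations, final KL=%.6g\n",
    ncol(x$metagenes), x$theta, x$iterations, x$final_objective))
  cat(sprintf("  W sparseness: %s\n",
              paste(sprintf("%.3f", x$sparseness), collapse = " ")))
  invisible(x)
}
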