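# From-scratch FastICA: whitening, symmetric fixed-point iteration with the
# tanh contrast, and multi-restart consensus with stability scoring.

# Coerce input to a plain samples x genes matrix with sample row names.
as_samples_by_genes <- function(data) {
  if (inherits(data, "mfgex_expr")) t(expr_values(data))
  else as.matrix(data)
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W.
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' Whiten a samples-by-genes matrix
#'
#' Centers each sample row across genes and applies an eigenvalue-based
#' whitening transform so the rows have zero mean and identity sample
#' covariance (n-1 denominator). Components with eigenvalue below
#' `1e-10 * max` are dropped with a warning (rank reduction); a
#' zero-variance row is an error.
#'
#' @param data an [expression_matrix()] or a plain samples x genes matrix.
#' @return a list with `whitened` (rank x genes matrix) and `record`
#'   (row means, whitening matrix `K`, `dewhiten` to undo the transform,
#'   retained `rank`, covariance `eigenvalues`).
#' @export
whiten <- function(data) {
  X <- as_samples_by_genes(data)
  m <- nrow(X)
  n <- ncol(X)
  if (m < 2 || n < 2)
    stop_mfgex("whitening needs >= 2 samples and >= 2 genes",
               class = "mfgex_degenerate_error")
  means <- rowMeans(X)
  Xc <- X - means
  if (any(rowSums(Xc^2) == 0))
    stop_mfgex("zero-variance sample row(s): ",
               paste(rownames(X)[rowSums(Xc^2) == 0], collapse = ", "),
               class = "mfgex_degenerate_error")
  C <- tcrossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > 1e-10 * e$values[1]
  r <- sum(keep)
  if (r < m)
    warning(sprintf("rank-deficient covariance: retaining %d of %d components",
                    r, m))
  vecs <- e$vectors[, keep, drop = FALSE]
  vals <- e$values[keep]
  K <- diag(1 / sqrt(vals), r) %*% t(vecs)
  dewhiten <- vecs %*% diag(sqrt(vals), r)
  list(whitened = K %*% Xc,
       record = list(row_means = means, K = K, dewhiten = dewhiten,
                     rank = r, eigenvalues = e$values,
                     sample_ids = rownames(X)))
}

# Overflow-safe log(cosh(x)).
logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# E[log cosh(a1 * g)] / a1 for standard normal g; negentropy-proxy baseline.
gauss_logcosh <- function(a1) {
  stats::integrate(function(u) logcosh(a1 * u) / a1 * stats::dnorm(u),
                   -Inf, Inf)$value
}

#' One FastICA run on whitened data
#'
#' Symmetric (parallel) fixed-point iteration with contrast derivative
#' `g(u) = tanh(a1 * u)` and symmetric decorrelation by inverse matrix
#' square root at every step. Convergence is declared when
#' `max_c |1 - |<w_new_c, w_old_c>||` falls below `tol`; otherwise the run
#' stops at `max_iter` with `converged = FALSE` and the caller decides.
#'
#' Stabilization: whenever the convergence measure fails to improve for 30
#' consecutive iterations, a single damped "stroke" step is taken (step
#' size `1/2^s` after `s` strokes, floored at 1/64) and the full step is
#' restored immediately afterwards. A one-off damped step breaks the orbit
#' cycling that weakly non-Gaussian (noise-dominated) components sustain
#' indefinitely, while keeping every fixed point and its stability type
#' intact — a permanently damped iteration would spuriously stabilize
#' mixture saddle points and degrade source recovery. Clean super-Gaussian
#' problems converge in a handful of full Newton steps and never stroke.
#'
#' @param whitened rank x genes matrix with identity row covariance (from
#'   [whiten()]).
#' @param a1 positive slope of the tanh contrast.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random orthonormal start.
#' @return a list with `unmixing` (orthonormal within 1e-8), `sources`
#'   (`unmixing %*% whitened`), `converged`, `iterations`, `strokes`,
#'   `seed`.
#' @export
fastica_once <- function(whitened, a1 = 1.0, tol = 1e-6, max_iter = 1000L,
                         seed = 1L) {
  Z <- as.matrix(whitened)
  r <- nrow(Z)
  n <- ncol(Z)
  W <- with_seed(seed, matrix(stats::rnorm(r * r), nrow = r))
  W <- sym_decorrelate(W)
  conv <- Inf
  iter <- 0L
  step <- 1
  best <- Inf
  stalled <- 0L
  strokes <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- W %*% Z
    G <- tanh(a1 * U)
    gprime_mean <- a1 * (1 - rowMeans(G^2))
    W_upd <- tcrossprod(G, Z) / n - gprime_mean * W
    W_new <- sym_decorrelate((1 - step) * W + step * W_upd)
    conv <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (conv < tol) break
    step <- 1  # strokes are one-off; always restore the full step
    if (conv < best) {
      best <- conv
      stalled <- 0L
    } else stalled <- stalled + 1L
    if (stalled >= 30L) {
      strokes <- strokes + 1L
      step <- 1 / 2^min(strokes, 6L)
      stalled <- 0L
    }
  }
  list(unmixing = W, sources = W %*% Z, converged = conv < tol,
       iterations = iter, strokes = strokes, seed = seed)
}

# Greedy one-to-one matching of source rows by absolute Pearson correlation.
# Returns, per reference component, the matched row index of `sources`, the
# absolute correlation, and the correlation sign.
greedy_match <- function(ref_sources, sources) {
  norm_rows <- function(M) {
    Mc <- M - rowMeans(M)
    Mc / sqrt(rowSums(Mc^2))
  }
  C <- tcrossprod(norm_rows(ref_sources), norm_rows(sources))
  A <- abs(C)
  r <- nrow(A)
  match_idx <- integer(r)
  match_r <- numeric(r)
  match_sign <- numeric(r)
  for (step in seq_len(min(r, ncol(A)))) {
    pos <- arrayInd(which.max(A), dim(A))
    i <- pos[1]; j <- pos[2]
    match_idx[i] <- j
    match_r[i] <- A[i, j]
    match_sign[i] <- sign(C[i, j])
    A[i, ] <- -1
    A[, j] <- -1
  }
  list(index = match_idx, abs_r = match_r, sign = match_sign)
}

#' Consensus FastICA over random restarts
#'
#' Runs [fastica_once()] for `ica_n_restarts` derived sub-seeds, matches
#' components across converged runs to the first converged run by greedy
#' absolute-correlation pairing, scores each component's stability as the
#' mean |r| to its matched partners, and returns the converged run with the
#' highest mean stability. The mixing matrix is recovered through the
#' whitening record and a sign convention (nonnegative skewness per source
#' row) fixes the up/down orientation of every mode.
#'
#' @param data standardized expression data ([expression_matrix()] or plain
#'   samples x genes matrix).
#' @param config a [run_config()].
#' @return an `mfgex_ica` object: `mixing` (samples x components), `sources`
#'   (components x genes, unit variance rows, nonnegative skewness),
#'   `whitening` record, per-component `stability` in `[0, 1]`,
#'   `objective` (negentropy proxy per component), `restart_count`,
#'   `n_converged`, `best_restart`.
#' @export
fastica_consensus <- function(data, config = run_config()) {
  X <- as_samples_by_genes(data)
  wh <- whiten(X)
  Z <- wh$whitened
  runs <- lapply(seq_len(config$ica_n_restarts), function(r) {
    fastica_once(Z, a1 = config$a1, tol = config$ica_tol,
                 max_iter = config$ica_max_iter,
                 seed = derive_seed(config$seed, "ica", r))
  })
  conv_idx <- which(vapply(runs, `[[`, logical(1), "converged"))
  if (length(conv_idx) == 0)
    stop_mfgex("no FastICA restart converged in ", config$ica_max_iter,
               " iterations; increase ica_max_iter or ica_tol",
               class = "mfgex_convergence_error")
  ref <- runs[[conv_idx[1]]]
  r <- nrow(ref$sources)
  matches <- lapply(conv_idx, function(i) greedy_match(ref$sources,
                                                       runs[[i]]$sources))
  abs_r <- vapply(matches, `[[`, numeric(r), "abs_r")
  abs_r <- matrix(abs_r, nrow = r)
  stability_ref <- rowMeans(abs_r)
  run_score <- colMeans(abs_r)
  best_pos <- which.max(run_score)
  best <- runs[[conv_idx[best_pos]]]
  best_match <- matches[[best_pos]]
  # stability per component of the selected run, mapped through its matching
  stability <- numeric(r)
  stability[best_match$index] <- stability_ref
  S <- best$sources
  A <- wh$record$dewhiten %*% t(best$unmixing)
  flip <- vapply(seq_len(r), function(c) row_skewness(S[c, ]) < 0, logical(1))
  S[flip, ] <- -S[flip, , drop = FALSE]
  A[, flip] <- -A[, flip, drop = FALSE]
  gc_base <- gauss_logcosh(config$a1)
  objective <- vapply(seq_len(r), function(c) {
    (mean(logcosh(config$a1 * S[c, ])) / config$a1 - gc_base)^2
  }, numeric(1))
  rownames(A) <- wh$record$sample_ids
  colnames(A) <- sprintf("IC%d", seq_len(r))
  rownames(S) <- sprintf("IC%d", seq_len(r))
  colnames(S) <- colnames(X)
  structure(list(mixing = A, sources = S, whitening = wh$record,
                 stability = stability, objective = objective,
                 restart_count = config$ica_n_restarts,
                 n_converged = length(conv_idx),
                 best_restart = conv_idx[best_pos]),
            class = "mfgex_ica")
}

#' @export
print.mfgex_ica <- function(x, ...) {
  cat(sprintf(
    "<mfgex_ica> %d components over %d genes; %d/%d restarts converged\n",
    nrow(x$sources), ncol(x$sources), x$n_converged, x$restart_count))
  cat(sprintf("  stability: %s\n",
              paste(sprintf("%.3f", x$stability), collapse = " ")))
  invisible(x)
}
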