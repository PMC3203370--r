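# Internal helpers: seeding, RNG hygiene, numeric formatting.

# Fixed stage offsets keep per-restart substreams from colliding across
# pipeline stages while remaining a pure function of the run seed.
.STAGE_OFFSET <- c(simulate = 0L, ica = 100000L, nsnmf = 200000L)

#' Derive a reproducible sub-seed from a run seed
#'
#' Restart `r` of a given stage always maps to the same sub-seed, so any
#' restart can be re-run in isolation. Result is kept inside the 32-bit
#' integer range.
#'
#' @param seed integer run seed.
#' @param stage one of `"simulate"`, `"ica"`, `"nsnmf"`.
#' @param restart restart index (1-based).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, stage = "ica", restart = 1L) {
  offset <- .STAGE_OFFSET[[stage]]
  as.integer((as.numeric(seed) + as.numeric(offset) + as.numeric(restart)) %%
               2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic text rendering of numerics (>= 15 significant digits) used by
# every writer, so identical results give byte-identical files.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

# Sample skewness (n denominator); used for the ICA sign convention.
row_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

stop_mfgex <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mfgex_error")))
}
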