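# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a root seed and a stream name, so that
# e.g. adding a drive realization never changes the sampled network.  Keeps
# results < 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_ecoguilds <- function(..., class = "ecoguilds_error") {
  rlang::abort(paste0(...), class = class)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1
}

# Upper-triangle (i < j) values of a square matrix, as a vector.
upper_pairs <- function(m) m[upper.tri(m)]

# Pair index tibble for an N x N matrix, i < j.
pair_index <- function(n, ids = NULL) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- tibble::tibble(i = idx[, "row"], j = idx[, "col"])
  if (!is.null(ids)) {
    out$taxon_i <- ids[out$i]
    out$taxon_j <- ids[out$j]
  }
  out
}
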