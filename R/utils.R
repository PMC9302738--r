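# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-facing seed per realization is
# split into independent streams (topology, strengths, initial conditions) so
# that e.g. topology is held fixed when only sigma varies. Kept below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 2011 + 7919 * as.numeric(stream)) %% 2147483629)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Extract CSR arrays (0-based) of a symmetric sparse/dense interaction matrix.
# For a symmetric matrix the CSC slots of a dgCMatrix double as CSR.
matrix_csr <- function(M) {
  M <- methods::as(methods::as(methods::as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  list(row_ptr = M@p, col_idx = M@i, values = M@x, n = nrow(M))
}
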