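# Internal helpers shared across modules.

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

is_whole <- function(x, tol = 0) {
  is.finite(x) & abs(x - round(x)) <= tol
}

# Derive a reproducible sub-stream seed from a user seed and a component
# offset, keeping the result inside the 32-bit signed-integer range.
# Separate sub-streams per component guarantee that e.g. adding genes to a
# simulated matrix never perturbs sample-level draws.
substream_seed <- function(seed, offset) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop2("a seed is mandatory: pass an integer 'seed'")
  }
  as.integer((as.numeric(seed) %% 1e6) * 2039L + 7919L * offset) %% 2147483647L
}

# Assert that 'x' is a genes x samples numeric matrix with unique,
# non-empty dimnames.
check_matrix_ids <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop2(what, " must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop2(what, " must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop2("duplicate gene ids in ", what, ": ",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop2("duplicate sample ids in ", what, ": ",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  invisible(x)
}
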