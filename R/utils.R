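# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that a master seed pins the whole pipeline.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hab <- function(...) stop(..., call. = FALSE)

check_same_geometry <- function(a_dim, a_sp, b_dim, b_sp, what = "inputs",
                                tol = 1e-6) {
  if (!identical(as.integer(a_dim), as.integer(b_dim))) {
    stop_hab(sprintf("%s have mismatched grid shapes (%s vs %s)", what,
                     paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  }
  if (max(abs(as.numeric(a_sp) - as.numeric(b_sp))) > tol) {
    stop_hab(sprintf("%s have mismatched voxel spacing", what))
  }
  invisible(TRUE)
}
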