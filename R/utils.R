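# Small internal helpers shared across modules.

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

# Evaluate `expr` under a private RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# All volumes in one analysis must share a voxel grid.
check_same_dim <- function(..., what = "volumes") {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(ok)) {
    stop(sprintf("%s are not co-registered: voxel grids differ", what), call. = FALSE)
  }
  invisible(ref)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
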