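# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Write `writer(path)` atomically: stage in a sibling temp file, then rename.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("could not move staged output to '%s'", path),
          class = "photomux_io_error")
  }
  invisible(path)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "photomux_config_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name),
          class = "photomux_config_error")
  }
  invisible(x)
}
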