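# internal helpers

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derived seed streams: keep below 2^31 - 1
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 48271 + k) %% 2147483647
  as.integer(s)
}

stopifnot_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
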