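# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# string key for integer index triples, used for hash joins on hkl
hkl_key <- function(h) {
  h <- as_hkl_matrix(h)
  paste(h[, 1L], h[, 2L], h[, 3L], sep = ",")
}

as_hkl_matrix <- function(h) {
  if (is.null(dim(h))) h <- matrix(as.integer(h), ncol = 3L, byrow = FALSE,
                                   nrow = length(h) / 3L)
  storage.mode(h) <- "integer"
  h
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# wrap angle to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + 1e-300] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
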