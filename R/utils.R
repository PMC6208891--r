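# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of distinct 32-bit sub-seeds from one master seed.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_mark_matrix <- function(m, d) {
  if (is.null(dim(m))) {
    m <- if (d == 1L) matrix(as.numeric(m), ncol = 1L)
         else matrix(as.numeric(m), ncol = d, byrow = TRUE)
  }
  m <- as.matrix(m)
  if (ncol(m) != d) stop(sprintf("marks must have dimension %d", d))
  m
}
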