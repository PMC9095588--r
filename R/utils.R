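# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream index.
sub_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + (abs(as.numeric(k)) %% 1e6) * 7 + 1) %% .Machine$integer.max
}

# FNV-1a 32-bit hash of a character scalar; used for provenance headers.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    p <- matrix(as.numeric(p), ncol = 3L)
  } else {
    if (ncol(p) != 3L) stop("points must be an n x 3 matrix")
    p <- matrix(as.numeric(as.matrix(p)), ncol = 3L)
  }
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

is_regular_times <- function(times, rel_tol = 1e-6) {
  if (length(times) < 2L) return(TRUE)
  dt <- diff(times)
  all(abs(dt - dt[1L]) <= rel_tol * abs(dt[1L]))
}
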