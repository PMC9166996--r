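## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream; a NULL/NA seed leaves the global stream in use.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Round half away from zero (base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

## Accept a GrayImage or a bare numeric matrix.
as_pixel_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is(x, "GrayImage")) return(x@pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("'", arg, "' must be a GrayImage or a numeric matrix")
}

## Reflect (half-sample symmetric) padding by r pixels on every side:
## nearest padded sample repeats the edge pixel.
pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  A <- nrow(m); B <- ncol(m)
  if (r > A || r > B)
    stop("padding radius exceeds image size")
  ri <- c(r:1, 1:A, A:(A - r + 1))
  ci <- c(r:1, 1:B, B:(B - r + 1))
  m[ri, ci, drop = FALSE]
}

## Derive a per-task child seed from a base seed, kept well below 2^31.
child_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (k in ix) s <- (s * 69069 + k) %% 2147483629
  as.integer(s)
}
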