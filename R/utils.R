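# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

# Squared distances from (x, y) to each row of (xs, ys).
distSq <- function(x, y, xs, ys) (xs - x)^2 + (ys - y)^2

# Logical mask of pixels whose centers lie within `radius` of the 0-based
# subpixel center (x, y); returns matrix indices (row, col) and count.
apertureIndices <- function(n, x, y, radius) {
  r <- ceiling(radius)
  cols <- max(1L, floor(x + 1 - r)):min(n, ceiling(x + 1 + r))
  rows <- max(1L, floor(y + 1 - r)):min(n, ceiling(y + 1 + r))
  cc <- rep(cols, each = length(rows))
  rr <- rep(rows, times = length(cols))
  keep <- ((cc - 1) - x)^2 + ((rr - 1) - y)^2 <= radius^2
  cbind(row = rr[keep], col = cc[keep])
}

# mode-dependent default choice helper
`%||%` <- function(a, b) if (is.null(a)) b else a
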