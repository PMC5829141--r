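## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. seed = NULL/NA means "use the
## current stream" (no isolation).
.with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## nearest index of `value` on grid `grid` (assumed uniform ascending)
.nearest_index <- function(grid, value) {
  which.min(abs(grid - value))
}

## closed-interval membership with a float-safe tolerance, so grid points
## that land exactly on a window boundary are never lost to rounding
.in_closed <- function(x, lo, hi, eps = 1e-9) {
  x >= lo - eps & x <= hi + eps
}
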