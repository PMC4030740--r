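`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluates expr under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards.  seed = NULL uses (and
# advances) the current RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
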