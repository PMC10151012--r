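# Seeded evaluation that restores the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Apply f to every numeric leaf of a nested parameter list.
mapLeaves <- function(x, f) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(f(x))
  if (is.list(x)) return(lapply(x, mapLeaves, f = f))
  x
}
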