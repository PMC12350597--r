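## Seed plumbing: all randomness in the package flows through explicit
## seeds; the global RNG state is saved and restored around every seeded
## computation so package calls never perturb a user's stream.

deriveSeed <- function(base, index = 0L) {
  as.integer((as.numeric(base) * 100003 + as.numeric(index) * 7919) %%
               2147483587)
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
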