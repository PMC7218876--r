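# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG state.  Every stochastic routine in the package funnels through this,
# which is what makes the fixed-seed reproducibility contract hold.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
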