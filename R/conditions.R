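# Classed conditions so callers (and tests) can distinguish failure modes.

staz_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "staz_error")))
}

staz_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "staz_warning")))
}

# internal seeded-evaluation helper: runs expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
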