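# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream-specific child seed from a base seed (kept below 2^31).
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 10007 * as.numeric(stream)) %%
               2147483629)
}
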