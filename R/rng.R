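# Seed management: one root seed is split deterministically into named
# subsystem streams (motion / photophysics / imaging), so e.g. changing the
# localization noise never perturbs the trajectories it annotates.

# Deterministic 31-bit sub-seed from a root seed and a stream label.
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(label)) h <- (h * 69069 + code) %% m
  as.integer(h)
}

# Create named RNG streams.  NULL seed means "use the ambient RNG":
# with_stream() then evaluates its body in the single global stream.
rng_streams <- function(seed, labels = c("motion", "photo", "imaging")) {
  if (is.null(seed)) return(NULL)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (lab in labels) {
    set.seed(derive_seed(seed, lab))
    assign(lab, get(".Random.seed", globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  env
}

# Evaluate `expr` under the named stream, saving the advanced state back.
with_stream <- function(streams, label, expr) {
  if (is.null(streams)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(label, envir = streams), envir = globalenv())
  on.exit({
    assign(label, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
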