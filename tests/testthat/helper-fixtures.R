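# Shared shorthand for tests.

fixture_pair <- function(name) {
  fx <- make_fixture(name)
  list(fx = fx, pair = build_pair_model(fx$models[[1]], fx$models[[2]]))
}

# random toy pair with guaranteed non-degenerate parameters drawn from the
# current RNG stream
draw_random_pair <- function() {
  np <- sample(0:2, 1); ns <- sample(0:2, 1)
  if (np == 0 && ns == 0) ns <- 1
  random_toy_pair(n_private = np, n_shared = ns,
                  n_crossfeed = sample(0:2, 1), depth = sample(1:2, 1),
                  yield = stats::runif(1, 0.5, 2))
}

# drop a random subset of present compounds from an environment (keeps at
# least `keep_min`); used to vary environments in property tests
thin_env <- function(env, keep_min = 1) {
  present <- env_compounds(env)
  if (length(present) <= keep_min) return(env)
  n_drop <- sample(0:(length(present) - keep_min), 1)
  if (n_drop == 0) return(env)
  env_remove(env, sample(present, n_drop))
}
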