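# Shared fixtures: random valid states/parameters under a fixed seed.

random_states <- function(n, seed = 42, max_abund = 500) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    make_state(sample(0:max_abund, 1), sample(0:max_abund, 1),
               sample(0:50, 1), sample(0:50, 1), sample(0:2000, 1)))
}

random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    re <- stats::runif(1, 0.5, 1)
    make_params(Qx = stats::runif(1, 0.3, 1), Qy = stats::runif(1, 0.3, 1),
                rp = stats::runif(1, 0.3, 1) * re, re = re,
                rx = stats::runif(1, 0.5, 1))
  })
}

# synthetic trajectory for summary/classification unit tests
synthetic_trajectory <- function(t, states, engine = "deterministic") {
  tritroph:::new_trajectory(t, states, engine = engine,
                            params = make_params())
}
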