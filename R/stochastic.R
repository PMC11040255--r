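# Exact stochastic simulation (Gillespie SSA).

#' Run one exact stochastic simulation
#'
#' Simulates the reaction network as a continuous-time Markov jump process
#' with the standard Gillespie algorithm: exponential waiting times at the
#' total propensity, channels chosen proportionally to their propensity.
#' States are recorded on a fixed sampling grid (`sample_dt`) rather than at
#' every event; event counts at realistic abundances are of order millions
#' per unit time span.  If every propensity reaches zero before `t_max`
#' (e.g. all populations absorbed at zero), the run terminates early and is
#' flagged `all_absorbed`.
#'
#' @param state0 integer-valued initial state (see [make_state()]).
#' @param p a `tri_params` object.
#' @param t_max simulation horizon (> 0).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param sample_dt recording grid spacing (default 0.1 time units).
#' @param max_events guard against runaway simulations.
#' @return a `tri_trajectory` with attributes `engine = "stochastic"`,
#'   `seed` and `terminated`.
#' @examples
#' p <- make_params()
#' tr <- gillespie_run(reference_state(), p, t_max = 2, seed = 1)
#' @export
gillespie_run <- function(state0, p, t_max, seed = NULL, sample_dt = 0.1,
                          max_events = 5e8) {
  stopifnot(inherits(p, "tri_params"))
  s0 <- check_integer_state(as_state(state0))
  if (t_max <= 0) stop("t_max must be positive")
  if (!is.null(seed)) set.seed(seed)
  res <- .Call(C_ssa_run, as.numeric(s0), as_param_vector(p),
               as.numeric(t_max), as.numeric(sample_dt),
               as.numeric(max_events))
  new_trajectory(res$t, res$states, engine = "stochastic", params = p,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 terminated = if (res$absorbed) "all_absorbed"
                              else "t_max_reached")
}

#' Run an ensemble of independent stochastic replicates
#'
#' Replicate `i` (1-based) uses seed `base_seed + i - 1`, so ensembles are
#' reproducible and order-independent: any subset of replicates can be
#' regenerated in isolation.
#'
#' @inheritParams gillespie_run
#' @param n_reps number of replicates (>= 1).
#' @param base_seed integer seed of the first replicate.
#' @return a list of `n_reps` trajectories.
#' @export
run_ensemble <- function(state0, p, t_max, n_reps, base_seed,
                         sample_dt = 0.1, max_events = 5e8) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(i)
    gillespie_run(state0, p, t_max, seed = base_seed + i - 1,
                  sample_dt = sample_dt, max_events = max_events))
}

#' Ensemble mean state at a given time
#'
#' Averages the state of each trajectory at the recorded time closest to
#' `at`, returning the componentwise mean and standard error across
#' replicates.
#'
#' @param trajs list of trajectories (e.g. from [run_ensemble()]).
#' @param at time at which to read the state.
#' @return list with vectors `mean` and `se`.
#' @export
ensemble_mean_state <- function(trajs, at) {
  states <- t(vapply(trajs, function(tr) {
    i <- which.min(abs(tr$t - at))
    unlist(tr[i, STATE_ORDER])
  }, numeric(5)))
  list(mean = colMeans(states),
       se = apply(states, 2, stats::sd) / sqrt(nrow(states)))
}
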