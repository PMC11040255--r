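# Outcome classification, parameter-plane sweeps and boundary bisection.

COEXISTENCE_LEVELS <- c("prey_only", "prey_predator", "all_three",
                        "none_survive")
COMPOSITION_LEVELS <- c("both_infected_dominant", "both_uninfected_dominant",
                        "predI_preyU_dominant", "predU_preyI_dominant",
                        "not_applicable")

#' Classify the long-run outcome of a run
#'
#' Coexistence: which of the three species persist.  In deterministic runs a
#' species is extinct when its tail-mean total abundance falls below
#' `extinction_threshold` (default one individual: the ODE state is strictly
#' positive, so extinction is a sub-individual cutoff).  In stochastic runs
#' extinction is an exact zero of the species total at the final state.
#'
#' Composition (only meaningful under three-species coexistence): compares
#' the tail-mean infected and uninfected subpopulations within each host.
#' A subtype dominates only if its tail mean is strictly larger; exact ties
#' count as uninfected-dominant.
#'
#' `none_survive` is a defensive label for the fully absorbed stochastic
#' state; it cannot occur deterministically with a viable prey.
#'
#' @param traj a `tri_trajectory` from either engine.
#' @param extinction_threshold deterministic extinction cutoff (abundance).
#' @param tail_fraction fraction of the time span averaged for the tail.
#' @return a `tri_outcome`: list with `coexistence` and `composition`.
#' @examples
#' tr <- ode_run(reference_state(), make_params(), t_max = 300)
#' classify_outcome(tr)
#' @export
classify_outcome <- function(traj, extinction_threshold = 1,
                             tail_fraction = 0.2) {
  stopifnot(inherits(traj, "tri_trajectory"))
  sm <- long_run_summary(traj, tail_fraction)
  m <- sm$mean
  if (attr(traj, "engine") == "stochastic") {
    fin <- unlist(traj[nrow(traj), STATE_ORDER])
    prey_alive <- (fin[["xU"]] + fin[["xI"]]) > 0
    pred_alive <- (fin[["yU"]] + fin[["yI"]]) > 0
    # the parasite persists through any of its life stages
    para_alive <- (fin[["z"]] + fin[["xI"]] + fin[["yI"]]) > 0
  } else {
    prey_alive <- (m[["xU"]] + m[["xI"]]) >= extinction_threshold
    pred_alive <- (m[["yU"]] + m[["yI"]]) >= extinction_threshold
    para_alive <- m[["z"]] >= extinction_threshold
  }
  coexistence <-
    if (!prey_alive && !pred_alive) "none_survive"
    else if (!pred_alive) "prey_only"
    else if (!para_alive) "prey_predator"
    else "all_three"
  composition <- "not_applicable"
  if (coexistence == "all_three") {
    prey_inf <- m[["xI"]] > m[["xU"]]
    pred_inf <- m[["yI"]] > m[["yU"]]
    composition <-
      if (prey_inf && pred_inf) "both_infected_dominant"
      else if (!prey_inf && !pred_inf) "both_uninfected_dominant"
      else if (pred_inf) "predI_preyU_dominant"
      else "predU_preyI_dominant"
  }
  structure(list(coexistence = coexistence, composition = composition),
            class = "tri_outcome")
}

#' @export
print.tri_outcome <- function(x, ...) {
  cat("<tri_outcome>", format(x), "\n")
  invisible(x)
}

#' @export
format.tri_outcome <- function(x, ...) {
  if (x$composition == "not_applicable") x$coexistence
  else paste0(x$coexistence, ":", x$composition)
}

#' Simulate one parameter set and classify it
#'
#' Convenience wrapper: run the chosen engine from `state0` and classify the
#' outcome.  Defaults follow the sweep protocol: horizon 2000 for the
#' deterministic engine, 1000 for the stochastic one, tail fraction 0.2,
#' extinction cutoff 1.
#'
#' @param p a `tri_params` object.
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param state0 initial state (default [reference_state()]).
#' @param t_max horizon; `NULL` for the engine default.
#' @param seed seed for the stochastic engine.
#' @param sample_dt recording grid (default 0.5).
#' @param extinction_threshold,tail_fraction passed to [classify_outcome()].
#' @return a `tri_outcome`.
#' @export
run_outcome <- function(p, engine = c("deterministic", "stochastic"),
                        state0 = reference_state(), t_max = NULL,
                        seed = NULL, sample_dt = 0.5,
                        extinction_threshold = 1, tail_fraction = 0.2) {
  engine <- match.arg(engine)
  if (is.null(t_max)) t_max <- if (engine == "deterministic") 2000 else 1000
  traj <- if (engine == "deterministic")
    ode_run(state0, p, t_max, sample_dt = sample_dt)
  else
    gillespie_run(state0, p, t_max, seed = seed, sample_dt = sample_dt)
  classify_outcome(traj, extinction_threshold, tail_fraction)
}

#' Relative frequency of outcome labels in an ensemble
#'
#' @param labels nonempty list of `tri_outcome` objects.
#' @return named numeric vector of relative frequencies (sums to 1).
#' @export
aggregate_ensemble <- function(labels) {
  if (!length(labels)) stop("empty label list")
  lab <- vapply(labels, format, character(1))
  tab <- table(lab)
  stats::setNames(as.numeric(tab) / length(lab), names(tab))
}

#' Sweep a two-parameter plane and classify every cell
#'
#' For each grid cell the chosen parameters are substituted into `base`, the
#' system is run and classified.  The deterministic engine yields one label
#' per cell; the stochastic engine yields label frequencies over `n_reps`
#' independent replicates (cell `k`, replicate `j` uses seed
#' `base_seed + (k - 1) * n_reps + j - 1`, so cells are independent and
#' order-insensitive).
#'
#' @param base a `tri_params` object.
#' @param axis1,axis2 parameter names (fields of the parameter set).
#' @param grid1,grid2 numeric grids for the two axes.
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param n_reps stochastic replicates per cell.
#' @param base_seed stochastic seed base.
#' @param t_max horizon; `NULL` for the engine default.
#' @param state0 initial state.
#' @param extinction_threshold,tail_fraction classification settings.
#' @param sample_dt recording grid.
#' @return a long-format data frame with columns `axis1`, `axis2` (named
#'   after the swept parameters), `label` and `frequency`, with sweep
#'   metadata in attributes.
#' @export
sweep_plane <- function(base, axis1, grid1, axis2, grid2,
                        engine = c("deterministic", "stochastic"),
                        n_reps = 100, base_seed = 1, t_max = NULL,
                        state0 = reference_state(),
                        extinction_threshold = 1, tail_fraction = 0.2,
                        sample_dt = 0.5) {
  engine <- match.arg(engine)
  stopifnot(inherits(base, "tri_params"))
  for (ax in c(axis1, axis2))
    if (!ax %in% PARAM_ORDER) stop("invalid axis name: ", ax)
  cells <- expand.grid(v1 = grid1, v2 = grid2, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    p <- update_params(base,
                       stats::setNames(list(cells$v1[k], cells$v2[k]),
                                       c(axis1, axis2)))
    if (engine == "deterministic") {
      lab <- run_outcome(p, "deterministic", state0, t_max,
                         sample_dt = sample_dt,
                         extinction_threshold = extinction_threshold,
                         tail_fraction = tail_fraction)
      rows[[k]] <- data.frame(v1 = cells$v1[k], v2 = cells$v2[k],
                              label = format(lab), frequency = 1)
    } else {
      labs <- lapply(seq_len(n_reps), function(j)
        run_outcome(p, "stochastic", state0, t_max,
                    seed = base_seed + (k - 1L) * n_reps + j - 1L,
                    sample_dt = sample_dt,
                    extinction_threshold = extinction_threshold,
                    tail_fraction = tail_fraction))
      freq <- aggregate_ensemble(labs)
      rows[[k]] <- data.frame(v1 = cells$v1[k], v2 = cells$v2[k],
                              label = names(freq), frequency = freq)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(out)[1:2] <- c(axis1, axis2)
  attr(out, "meta") <- list(base = base, engine = engine,
                            n_reps = if (engine == "stochastic") n_reps else 1,
                            base_seed = base_seed,
                            t_max = if (is.null(t_max)) {
                              if (engine == "deterministic") 2000 else 1000
                            } else t_max)
  out
}

outcome_predicate <- function(predicate) {
  if (is.function(predicate)) return(predicate)
  if (predicate %in% COEXISTENCE_LEVELS)
    function(o) o$coexistence == predicate
  else if (predicate %in% COMPOSITION_LEVELS)
    function(o) o$composition == predicate
  else stop("unknown predicate: ", predicate)
}

#' Locate a deterministic outcome boundary by bisection
#'
#' Bisects one parameter between bracket endpoints at which a predicate on
#' the classified outcome disagrees, to a parameter tolerance (default
#' 0.005).  The predicate can be a coexistence level (e.g. `"all_three"`), a
#' composition level (e.g. `"both_infected_dominant"`), or any function of a
#' `tri_outcome` returning a logical.
#'
#' @param base a `tri_params` object.
#' @param axis parameter name to bisect.
#' @param predicate outcome condition (string or function).
#' @param bracket length-2 numeric interval.
#' @param tol bisection tolerance on the parameter.
#' @param ... passed to [run_outcome()] (engine, horizon, thresholds...).
#' @return the boundary parameter value (midpoint of the final bracket).
#' @examples
#' \donttest{
#' # minimal Qy for three-species coexistence, no reproductive costs
#' find_threshold(make_params(), "Qy", "all_three", c(0.05, 0.9))
#' }
#' @export
find_threshold <- function(base, axis, predicate, bracket, tol = 0.005, ...) {
  stopifnot(inherits(base, "tri_params"), length(bracket) == 2L)
  pred <- outcome_predicate(predicate)
  eval_at <- function(v)
    pred(run_outcome(update_params(base, stats::setNames(list(v), axis)), ...))
  lo <- min(bracket); hi <- max(bracket)
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (f_lo == f_hi)
    stop("predicate does not differ at the bracket endpoints")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_at(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Lower edge of a predicate region along one parameter
#'
#' Scans `axis` upward from `lower` in steps of `step` until the predicate
#' first holds, then refines the boundary between the last failing and first
#' satisfying values by bisection.  Suited to regions that are bands: a
#' plain two-point bracket would miss a band narrower than the bracket.
#' Returns `NA` if the predicate never holds on the scan.
#'
#' @inheritParams find_threshold
#' @param lower,upper scan range.
#' @param step scan step.
#' @return the refined lower edge of the region, or `NA_real_`.
#' @export
find_region_edge <- function(base, axis, predicate, lower, upper,
                             step = 0.02, tol = 0.005, ...) {
  pred <- outcome_predicate(predicate)
  eval_at <- function(v)
    pred(run_outcome(update_params(base, stats::setNames(list(v), axis)), ...))
  grid <- seq(lower, upper, by = step)
  prev <- lower
  for (v in grid) {
    if (eval_at(v)) {
      if (v == lower) return(lower)
      return(find_threshold(base, axis, predicate, c(prev, v), tol, ...))
    }
    prev <- v
  }
  NA_real_
}

#' Minimal parameter value of a region over a plane
#'
#' For each value of a companion parameter, finds the lower edge of the
#' predicate region along `axis` (scan plus bisection) and returns the
#' smallest edge over the companion grid -- the minimal `axis` value at
#' which the region appears anywhere in the plane, refined by bisection at
#' the most favourable companion value.
#'
#' @inheritParams find_region_edge
#' @param companion companion parameter name.
#' @param companion_grid values of the companion parameter to examine.
#' @return list with `value` (the minimum, `NA` if the region is empty),
#'   `at` (companion value attaining it) and `edges` (per-companion edges).
#' @export
find_region_min <- function(base, axis, predicate, lower, upper,
                            companion, companion_grid,
                            step = 0.02, tol = 0.005, ...) {
  edges <- vapply(companion_grid, function(cv) {
    b <- update_params(base, stats::setNames(list(cv), companion))
    find_region_edge(b, axis, predicate, lower, upper, step, tol, ...)
  }, numeric(1))
  if (all(is.na(edges)))
    return(list(value = NA_real_, at = NA_real_, edges = edges))
  i <- which.min(edges)
  list(value = edges[i], at = companion_grid[i],
       edges = stats::setNames(edges, companion_grid))
}
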