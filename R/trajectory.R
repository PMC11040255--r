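# Trajectory container shared by both engines.

new_trajectory <- function(t, states, engine, params, seed = NA,
                           terminated = "t_max_reached") {
  stopifnot(is.matrix(states), ncol(states) == 5L,
            length(t) == nrow(states))
  storage.mode(states) <- "double"
  df <- data.frame(t = as.numeric(t), states)
  names(df) <- c("t", STATE_ORDER)
  structure(df,
            class = c("tri_trajectory", "data.frame"),
            engine = engine, params = params,
            seed = as.integer(seed),
            terminated = terminated)
}

#' @export
print.tri_trajectory <- function(x, ...) {
  cat(sprintf("<tri_trajectory: %s engine, %d samples, t in [%g, %g], %s>\n",
              attr(x, "engine"), nrow(x), x$t[1], x$t[nrow(x)],
              attr(x, "terminated")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Time-averaged abundances over the tail of a trajectory
#'
#' Summarises the final portion of a run by the mean and minimum of each of
#' the five populations over the last `tail_fraction` of the simulated time
#' span.  On cyclic or noisy dynamics the tail mean is the quantity used for
#' long-run classification.
#'
#' @param traj a `tri_trajectory`.
#' @param tail_fraction fraction of the time span to average over, in (0, 1].
#' @return a list with named vectors `mean` and `min` and the window
#'   `window = c(from, to)`.
#' @export
long_run_summary <- function(traj, tail_fraction = 0.2) {
  stopifnot(inherits(traj, "tri_trajectory"))
  if (nrow(traj) < 1L) stop("empty trajectory")
  if (!(tail_fraction > 0 && tail_fraction <= 1))
    stop("tail_fraction must lie in (0, 1]")
  t0 <- traj$t[1]
  t1 <- traj$t[nrow(traj)]
  if (t1 <= t0 && nrow(traj) > 1L) stop("trajectory spans no time")
  from <- t1 - tail_fraction * (t1 - t0)
  keep <- traj$t >= from - 1e-12
  m <- as.matrix(traj[keep, STATE_ORDER, drop = FALSE])
  list(mean = colMeans(m),
       min = apply(m, 2, min),
       window = c(from = from, to = t1))
}
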