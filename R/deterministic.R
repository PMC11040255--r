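# Mean-field rate equations and their numerical integration.

#' Right-hand side of the mean-field rate equations
#'
#' The five coupled ODEs derived from the reaction network:
#' \deqn{\dot x_U = g_x (r_x x_I + x_U) - (x_I + x_U) x_U / K - d_x x_U
#'       - Q_x S x_U z - f_y x_U (y_I + y_U)}
#' \deqn{\dot x_I = -(x_I + x_U) x_I / K - d_x x_I + Q_x S x_U z
#'       - f_y x_I (y_I + y_U)}
#' \deqn{\dot y_U = k_y f_y x_U (r_p y_I + y_U)
#'       + (r_e k_y (1 - Q_y) - (1 - r_p k_y) Q_y) f_y x_I y_U
#'       + (r_p r_e k_y (1 - Q_y) + r_p^2 k_y Q_y) f_y x_I y_I - d_y y_U}
#' \deqn{\dot y_I = -d_y y_I + Q_y f_y x_I y_U}
#' \deqn{\dot z = -Q_x S x_U z + n_z Q_y f_y x_I (y_I + y_U) - d_z z}
#'
#' @param state nonnegative state vector (see [make_state()]).
#' @param p a `tri_params` object.
#' @return named derivative vector over `(xU, xI, yU, yI, z)`.
#' @export
ode_rhs <- function(state, p) {
  stopifnot(inherits(p, "tri_params"))
  s <- as_state(state)  # errors on negative components
  xU <- s[["xU"]]; xI <- s[["xI"]]; yU <- s[["yU"]]; yI <- s[["yI"]]
  z <- s[["z"]]
  with(p, c(
    xU = gx * (rx * xI + xU) - (xI + xU) * xU / K - dx * xU -
      Qx * S * xU * z - fy * xU * (yI + yU),
    xI = -(xI + xU) * xI / K - dx * xI + Qx * S * xU * z -
      fy * xI * (yI + yU),
    yU = ky * fy * xU * (rp * yI + yU) +
      (re * ky * (1 - Qy) - (1 - rp * ky) * Qy) * fy * xI * yU +
      (rp * re * ky * (1 - Qy) + rp^2 * ky * Qy) * fy * xI * yI -
      dy * yU,
    yI = -dy * yI + Qy * fy * xI * yU,
    z = -Qx * S * xU * z + nz * Qy * fy * xI * (yI + yU) - dz * z
  ))
}

#' Integrate the mean-field equations
#'
#' Adaptive stiff-capable integration (`deSolve::lsoda`) of the rate
#' equations, by default through the package's compiled right-hand side.
#' Abundance components that dip below zero by floating-point error are
#' clamped to zero both inside the derivative evaluation and in the returned
#' trajectory.  Tight tolerances are the default because classification
#' reads deep cyclic valleys where abundances fall far below one.
#'
#' @param state0 nonnegative initial state.
#' @param p a `tri_params` object.
#' @param t_max integration horizon (> 0).
#' @param sample_dt output grid spacing.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param compiled use the compiled rhs (`TRUE`, default) or the R-level
#'   [ode_rhs()] (slower; used for cross-validation).
#' @return a `tri_trajectory` with `engine = "deterministic"`.
#' @examples
#' tr <- ode_run(reference_state(), make_params(), t_max = 50)
#' @export
ode_run <- function(state0, p, t_max, sample_dt = 0.1,
                    rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  stopifnot(inherits(p, "tri_params"))
  s0 <- as_state(state0)
  if (t_max <= 0) stop("t_max must be positive")
  times <- seq(0, t_max, by = sample_dt)
  if (times[length(times)] < t_max) times <- c(times, t_max)

  solve_from <- function(y, tt) {
    # hmax stays unconstrained: the default (the output spacing) trips an
    # lsoda interpolation fault after cyclic deep-valley underflows
    if (compiled) {
      deSolve::lsoda(y = y, times = tt, func = "tritroph_derivs",
                     parms = as_param_vector(p), dllname = "tritroph",
                     initfunc = "tritroph_initmod",
                     rtol = rtol, atol = atol, maxsteps = 100000, hmax = Inf)
    } else {
      rhs_fn <- function(t, y, parms) {
        y <- pmax(y, 0)
        names(y) <- STATE_ORDER
        list(unname(ode_rhs(y, p)))
      }
      deSolve::lsoda(y = y, times = tt, func = rhs_fn, parms = NULL,
                     rtol = rtol, atol = atol, maxsteps = 100000, hmax = Inf)
    }
  }

  # integrate, restarting from the last good state (components below the
  # clamping tolerance zeroed) if the solver stalls mid-run
  rows <- matrix(numeric(0), ncol = 6)
  todo <- times
  y <- unname(s0)
  for (attempt in 1:5) {
    out <- tryCatch(suppressWarnings(solve_from(y, todo)),
                    error = function(e) NULL)
    got <- if (is.null(out)) 1L else nrow(out)
    if (got > 1L) rows <- rbind(rows, unname(out[-1, , drop = FALSE]))
    done_t <- if (nrow(rows)) rows[nrow(rows), 1] else 0
    if (got == length(todo)) break
    if (attempt == 5L || nrow(rows) == 0L)
      stop(sprintf("integration failed at t = %g (of %g)", done_t, t_max))
    y <- rows[nrow(rows), -1]
    y[y < 1e-12] <- 0
    todo <- c(done_t, times[times > done_t])
  }
  states <- pmax(rows[, -1, drop = FALSE], 0)
  new_trajectory(c(0, rows[, 1]), rbind(unname(s0), states * 1),
                 engine = "deterministic", params = p)
}
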