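# Equilibrium analysis: parasite-free point, interior equilibria via the
# polynomial condition on the infected-prey abundance, and a numerical
# parasite-invasion growth rate.

#' Derived coefficients of the equilibrium analysis
#'
#' Compound rates appearing in the steady-state algebra:
#' `alpha = Qx * S`, `beta = Qy * fy`, `gamma = rp * ky * fy`,
#' `delta = ky * fy`,
#' `epsilon = (re * ky * (1 - Qy) - (1 - rp * ky) * Qy) * fy`,
#' `zeta = (rp * re * ky * (1 - Qy) + rp^2 * ky * Qy) * fy`,
#' `eta = nz * Qy * fy` and `lambda = beta / dy`.
#' All are nonnegative except `epsilon`, which can take either sign.
#'
#' @param p a `tri_params` object.
#' @return named list of the eight coefficients.
#' @export
derived_coefficients <- function(p) {
  stopifnot(inherits(p, "tri_params"))
  with(p, {
    beta <- Qy * fy
    list(
      alpha = Qx * S,
      beta = beta,
      gamma = rp * ky * fy,
      delta = ky * fy,
      epsilon = (re * ky * (1 - Qy) - (1 - rp * ky) * Qy) * fy,
      zeta = (rp * re * ky * (1 - Qy) + rp^2 * ky * Qy) * fy,
      eta = nz * Qy * fy,
      lambda = beta / dy
    )
  })
}

# intermediate functions of the candidate infected-prey abundance xI
equilibrium_pieces <- function(xI, p, co = derived_coefficients(p)) {
  denom <- co$gamma * co$lambda * xI + co$delta
  if (any(abs(denom) < 1e-300))
    stop("pole: gamma * lambda * xI + delta vanishes")
  Phi <- co$lambda * xI + 1
  Psi <- (p$dy - co$epsilon * xI - co$zeta * co$lambda * xI^2) / denom
  Theta <- co$alpha * Psi + p$dz
  list(Phi = Phi, Psi = Psi, Theta = Theta, co = co)
}

#' Steady-state polynomial residual in the infected-prey abundance
#'
#' An interior equilibrium requires the infected-prey abundance `xI` to be a
#' root of a polynomial condition built from the intermediate functions
#' `Phi = lambda * xI + 1`,
#' `Psi = (dy - epsilon * xI - zeta * lambda * xI^2) /
#'        (gamma * lambda * xI + delta)` and
#' `Theta = alpha * Psi + dz`:
#' \deqn{\Theta\big[(x_I + \Psi + K d_x)(K \Phi \Psi \alpha \eta x_I
#'   + K \Theta \Phi \Psi f_y)
#'   - (K g_x (r_x x_I + \Psi) - \Psi (x_I + \Psi + K d_x))
#'     (K \Phi \Psi \alpha \eta - K \Theta \Phi f_y)\big] = 0}
#' This function evaluates the left-hand side; [solve_interior_equilibria()]
#' scans it for sign changes.
#'
#' @param xI candidate infected-prey abundance (> 0).
#' @param p a `tri_params` object.
#' @return the residual (scalar, any sign).
#' @export
polynomial_residual <- function(xI, p) {
  stopifnot(inherits(p, "tri_params"))
  pieces <- equilibrium_pieces(xI, p)
  co <- pieces$co
  Phi <- pieces$Phi; Psi <- pieces$Psi; Theta <- pieces$Theta
  K <- p$K
  Theta * ((xI + Psi + K * p$dx) *
             (K * Phi * Psi * co$alpha * co$eta * xI +
                K * Theta * Phi * Psi * p$fy) -
           (K * p$gx * (p$rx * xI + Psi) - Psi * (xI + Psi + K * p$dx)) *
             (K * Phi * Psi * co$alpha * co$eta - K * Theta * Phi * p$fy))
}

# back-substitute the remaining populations from a root xI of the polynomial
back_substitute <- function(xI, p) {
  pieces <- equilibrium_pieces(xI, p)
  co <- pieces$co
  Phi <- pieces$Phi; Psi <- pieces$Psi; Theta <- pieces$Theta
  K <- p$K
  xU <- Psi
  den1 <- K * Phi * co$alpha * co$eta * xU - K * Theta * Phi * p$fy
  yU1 <- if (abs(den1) > 1e-300)
    Theta * (xI + xU + K * p$dx) / den1 else NA_real_
  den2 <- K * Phi * co$alpha * co$eta * xI * xU + K * Theta * Phi * p$fy * xU
  yU2 <- if (abs(den2) > 1e-300)
    (K * Theta * p$gx * (p$rx * xI + xU) -
       Theta * (xI + xU + K * p$dx) * xU) / den2 else NA_real_
  yU <- if (is.finite(yU1)) yU1 else yU2
  yI <- co$lambda * xI * yU
  z <- if (abs(Theta) > 1e-300)
    co$eta * xI * (yI + yU) / Theta else NA_real_
  list(state = c(xU = xU, xI = xI, yU = yU, yI = yI, z = z),
       yU_forms = c(yU1, yU2))
}

#' Locate interior (three-species) equilibria
#'
#' Scans the polynomial residual over a log-dense grid of candidate
#' infected-prey abundances in `(0, x_upper]`, polishes every sign change
#' with bisection-based root finding, back-substitutes the remaining four
#' populations, and keeps only points with all five components strictly
#' positive whose full rate-equation residual (max-norm of [ode_rhs()]) is
#' below `rhs_tol`.  The rhs check is the acceptance authority; the
#' polynomial only proposes candidates, guarding against spurious roots from
#' cleared denominators.  An empty list is a valid outcome: no interior
#' equilibrium exists (e.g. whenever `Qy = 0`, since the parasite cannot
#' reproduce).
#'
#' @param p a `tri_params` object.
#' @param x_upper scan upper bound (default the carrying capacity `K`).
#' @param n_scan number of log-spaced scan points.
#' @param rhs_tol acceptance tolerance on the rate-equation max-norm.
#' @return list of equilibrium points; each has `state` (named vector),
#'   `residual` (rhs max-norm), `yU_forms` (the two printed algebraic forms
#'   of the uninfected-predator abundance, for consistency diagnostics) and
#'   `stable_hint = "not_assessed"`.
#' @export
solve_interior_equilibria <- function(p, x_upper = p$K, n_scan = 4000,
                                      rhs_tol = 1e-6) {
  stopifnot(inherits(p, "tri_params"))
  grid <- exp(seq(log(1e-6), log(x_upper), length.out = n_scan))
  vals <- vapply(grid, function(x)
    tryCatch(polynomial_residual(x, p), error = function(e) NA_real_),
    numeric(1))
  roots <- c()
  for (i in seq_len(n_scan - 1)) {
    v1 <- vals[i]; v2 <- vals[i + 1]
    if (!is.finite(v1) || !is.finite(v2)) next
    if (v1 == 0) { roots <- c(roots, grid[i]); next }
    if (sign(v1) * sign(v2) < 0) {
      r <- tryCatch(
        stats::uniroot(function(x) polynomial_residual(x, p),
                       lower = grid[i], upper = grid[i + 1],
                       tol = .Machine$double.eps^0.75)$root,
        error = function(e) NA_real_)
      if (is.finite(r)) roots <- c(roots, r)
    }
  }
  if (!length(roots)) return(list())
  # deduplicate near-identical roots
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) / pmax(roots[-length(roots)], 1e-12) > 1e-6)
  roots <- roots[keep]

  out <- list()
  for (r in roots) {
    bs <- tryCatch(back_substitute(r, p), error = function(e) NULL)
    if (is.null(bs)) next
    st <- bs$state
    if (any(!is.finite(st)) || any(st <= 0)) next
    res <- max(abs(ode_rhs(st, p)))
    if (!is.finite(res) || res > rhs_tol) next
    out[[length(out) + 1L]] <-
      list(state = st, residual = res, yU_forms = bs$yU_forms,
           stable_hint = "not_assessed")
  }
  out
}

#' Parasite-free (two-species) equilibrium
#'
#' Without the parasite the system is a damped Lotka-Volterra pair with the
#' closed-form equilibrium `xU* = dy / (ky * fy)` and
#' `yU* = (gx - dx - xU* / K) / fy`; infected compartments and parasites are
#' zero.  Requires the predator to be viable, i.e.
#' `gx - dx - dy / (ky * fy * K) > 0`.
#'
#' @param p a `tri_params` object.
#' @return an equilibrium point (same shape as the entries of
#'   [solve_interior_equilibria()]).
#' @examples
#' parasite_free_equilibrium(make_params())$state  # xU* = 500, yU* = 165
#' @export
parasite_free_equilibrium <- function(p) {
  stopifnot(inherits(p, "tri_params"))
  if (p$ky * p$fy <= 0)
    stop("predator not viable: ky * fy must be positive")
  xU <- p$dy / (p$ky * p$fy)
  yU <- (p$gx - p$dx - xU / p$K) / p$fy
  if (yU <= 0)
    stop("predator not viable: gx - dx - dy / (ky * fy * K) must be positive")
  st <- c(xU = xU, xI = 0, yU = yU, yI = 0, z = 0)
  list(state = st, residual = max(abs(ode_rhs(st, p))),
       yU_forms = c(yU, yU), stable_hint = "not_assessed")
}

#' Numerical parasite invasion growth rate
#'
#' Linearises the infected subsystem `(xI, yI, z)` around the parasite-free
#' equilibrium and returns the dominant eigenvalue's real part.  A positive
#' value means a rare parasite grows in expectation and can invade the
#' predator-prey system; with `Qx = 0` or `Qy = 0` a transmission link is
#' missing and the rate is nonpositive.
#'
#' @param p a `tri_params` object.
#' @return the dominant linearised growth rate (scalar).
#' @export
invasion_growth_rate <- function(p) {
  eq <- parasite_free_equilibrium(p)$state
  xU <- eq[["xU"]]; yU <- eq[["yU"]]
  J <- with(p, matrix(c(
    -(xU / K + dx + fy * yU), 0,   Qx * S * xU,
    Qy * fy * yU,             -dy, 0,
    nz * Qy * fy * yU,        0,   -(Qx * S * xU + dz)
  ), nrow = 3, byrow = TRUE))
  max(Re(eigen(J, only.values = TRUE)$values))
}
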