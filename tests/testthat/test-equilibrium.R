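test_that("derived coefficients follow their printed definitions", {
  co <- derived_coefficients(make_params())
  expect_equal(co$alpha, 1 * 5e-4)
  expect_equal(co$beta, 1 * 0.01)
  expect_equal(co$delta, 0.2 * 0.01)
  expect_equal(co$lambda, 0.01 / 1)
  # no reproductive costs, certain predator infection
  expect_equal(co$epsilon, -(1 - 0.2) * 0.01)
  expect_equal(co$zeta, 0.2 * 0.01)
  co0 <- derived_coefficients(make_params(Qy = 0))
  expect_equal(co0$beta, 0)
  expect_equal(co0$eta, 0)
  expect_equal(co0$epsilon, 1 * 0.2 * 0.01)
})

test_that("the parasite-free equilibrium has its closed form", {
  p <- make_params()
  eq <- parasite_free_equilibrium(p)
  expect_equal(unname(eq$state),
               c(500, 0, 165, 0, 0))
  expect_lt(eq$residual, 1e-10)
  # prey equilibrium scales as 1/fy
  eq2 <- parasite_free_equilibrium(make_params(fy = 0.02))
  expect_equal(eq2$state[["xU"]], 250)
  # predator non-viability is an error
  expect_error(parasite_free_equilibrium(make_params(fy = 1e-4)),
               "viable")
})

test_that("interior equilibrium matches the long-run rate-equation state", {
  p <- make_params()
  eqs <- solve_interior_equilibria(p)
  expect_gte(length(eqs), 1L)
  tr <- ode_run(reference_state(), p, 2000, sample_dt = 0.5)
  tail_mean <- long_run_summary(tr)$mean
  err <- vapply(eqs, function(e)
    max(abs(e$state - tail_mean) / tail_mean), numeric(1))
  best <- eqs[[which.min(err)]]
  expect_lt(min(err), 0.01)
  expect_lt(best$residual, 1e-6)
  # both printed algebraic forms of the uninfected-predator abundance agree
  expect_equal(best$yU_forms[1], best$yU_forms[2], tolerance = 1e-6)
  # the accepted root solves the polynomial: tiny against its local scale
  xI <- best$state[["xI"]]
  scale <- abs(polynomial_residual(xI * 1.01, p)) +
    abs(polynomial_residual(xI * 0.99, p))
  expect_lt(abs(polynomial_residual(xI, p)) / scale, 1e-6)
})

test_that("no interior equilibrium exists without predator infection", {
  expect_length(solve_interior_equilibria(make_params(Qy = 0)), 0L)
})

test_that("a dense brute-force scan finds no extra sign changes", {
  count_sign_changes <- function(p, n) {
    grid <- exp(seq(log(1e-6), log(p$K), length.out = n))
    v <- vapply(grid, function(x) polynomial_residual(x, p), numeric(1))
    s <- sign(v[is.finite(v)])
    sum(s[-1] * s[-length(s)] < 0)
  }
  for (p in list(make_params(), make_params(Qy = 0.5, rp = 0.8),
                 make_params(Qx = 0.3))) {
    expect_equal(count_sign_changes(p, 1e5), count_sign_changes(p, 4000))
  }
})

test_that("converged dynamics land on a computed equilibrium point", {
  for (p in random_params(8, seed = 2024)) {
    tr <- ode_run(reference_state(), p, 2000, sample_dt = 0.5)
    sm <- long_run_summary(tr)
    m <- as.matrix(as.data.frame(tr)[-1])
    tail_rows <- m[tr$t >= 0.8 * 2000, , drop = FALSE]
    rel_var <- max(apply(tail_rows, 2, stats::sd) / pmax(sm$mean, 1e-8))
    converged <- rel_var < 1e-3 && all(sm$mean > 1)
    if (!converged) next
    eqs <- solve_interior_equilibria(p)
    expect_gte(length(eqs), 1L)
    err <- vapply(eqs, function(e)
      max(abs(e$state - sm$mean) / sm$mean), numeric(1))
    expect_lt(min(err), 0.01)
    # both yU* forms agree at every accepted root
    for (e in eqs)
      expect_equal(e$yU_forms[1], e$yU_forms[2], tolerance = 1e-6)
  }
})

test_that("invasion requires both transmission links", {
  expect_gt(invasion_growth_rate(make_params()), 0)
  expect_lte(invasion_growth_rate(make_params(Qy = 0)), 0)
  expect_lte(invasion_growth_rate(make_params(Qx = 0)), 0)
})
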