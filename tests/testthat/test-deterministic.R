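test_that("the rate equations evaluate to the hand-computed derivatives", {
  p <- make_params()
  # every term carries a state factor
  expect_equal(ode_rhs(make_state(0, 0, 0, 0, 0), p),
               c(xU = 0, xI = 0, yU = 0, yI = 0, z = 0))
  # the two-species closed-form equilibrium is a fixed point
  expect_lt(max(abs(ode_rhs(make_state(500, 0, 165, 0, 0), p))), 1e-12)
  # reference initial state: dxI = Qx*S*xU*z = 400, and the rest by hand
  d <- ode_rhs(reference_state(), p)
  expect_equal(unname(d["xI"]), 0.0005 * 800 * 1000)
  expect_equal(unname(d["xU"]), 2 * 800 - 800^2 / 2000 - 0.1 * 800 -
                 400 - 0.01 * 800 * 100)
  expect_equal(unname(d["yU"]), 0.2 * 0.01 * 800 * 100 - 100)
  expect_equal(unname(d["yI"]), 0)
  expect_equal(unname(d["z"]), -400 - 0.09 * 1000)
  expect_error(ode_rhs(c(xU = -1, xI = 0, yU = 0, yI = 0, z = 0), p),
               "nonnegative")
})

test_that("compiled and R-level right-hand sides integrate identically", {
  p <- make_params(Qy = 0.6, rp = 0.7, re = 0.9, rx = 0.8)
  a <- ode_run(reference_state(), p, 20, sample_dt = 0.5)
  b <- ode_run(reference_state(), p, 20, sample_dt = 0.5, compiled = FALSE)
  m_a <- as.matrix(as.data.frame(a)[-1])
  m_b <- as.matrix(as.data.frame(b)[-1])
  expect_lt(max(abs(m_a - m_b) / (abs(m_a) + 1)), 1e-6)
})

test_that("without the parasite the system is damped Lotka-Volterra", {
  p <- make_params()
  tr <- ode_run(make_state(800, 0, 100, 0, 0), p, 2000, sample_dt = 0.5)
  fin <- unlist(tr[nrow(tr), tritroph:::STATE_ORDER])
  expect_equal(fin[["xU"]], 500, tolerance = 1e-6)
  expect_equal(fin[["yU"]], 165, tolerance = 1e-6)
  expect_equal(fin[["xI"]] + fin[["yI"]] + fin[["z"]], 0)
})

test_that("breaking either transmission link extinguishes the parasite", {
  for (p in list(make_params(Qx = 0), make_params(Qy = 0))) {
    tr <- ode_run(reference_state(), p, 2000, sample_dt = 0.5)
    sm <- long_run_summary(tr)
    expect_lt(sm$mean[["z"]], 1e-3)
    expect_equal(classify_outcome(tr)$coexistence, "prey_predator")
  }
})

test_that("full predator sterilisation gives cycles that stay positive", {
  # deep valleys, but the deterministic flow never reaches zero while the
  # abundances remain representable
  tr <- ode_run(reference_state(), make_params(rp = 0), 300, sample_dt = 0.5)
  m <- as.matrix(as.data.frame(tr)[-1])
  expect_true(all(m > 0 | row(m) == 1))
  expect_lt(min(m[-1, "yU"]), 1)  # the valleys dip below one individual
})

test_that("long_run_summary averages the tail window", {
  const <- synthetic_trajectory(0:100, matrix(rep(c(5, 3, 2, 1, 7),
                                                  each = 101), ncol = 5))
  sm <- long_run_summary(const, 0.2)
  expect_equal(unname(sm$mean), c(5, 3, 2, 1, 7))
  expect_equal(sm$mean, sm$min)
  # sine plus offset averages to the offset over whole periods
  t <- seq(0, 100, by = 0.01)
  wave <- 10 + sin(2 * pi * t)
  sine <- synthetic_trajectory(t, cbind(wave, wave, wave, wave, wave))
  expect_equal(unname(long_run_summary(sine, 0.5)$mean),
               rep(10, 5), tolerance = 1e-3)
  expect_error(long_run_summary(const, 0), "tail_fraction")
})
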