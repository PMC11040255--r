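test_that("reference dynamics classify as three-species coexistence", {
  p <- make_params()
  det <- run_outcome(p, "deterministic")
  expect_equal(det$coexistence, "all_three")
  sto <- run_outcome(p, "stochastic", t_max = 300, seed = 4)
  expect_equal(sto$coexistence, "all_three")
})

test_that("without predator infection only prey and predator persist", {
  out <- run_outcome(make_params(Qy = 0), "deterministic")
  expect_equal(out$coexistence, "prey_predator")
  expect_equal(out$composition, "not_applicable")
})

test_that("composition compares tail means, ties favouring uninfected", {
  tr_tie <- synthetic_trajectory(0:100,
    matrix(rep(c(10, 10, 5, 5, 50), each = 101), ncol = 5))
  expect_equal(classify_outcome(tr_tie)$composition,
               "both_uninfected_dominant")
  tr_mix <- synthetic_trajectory(0:100,
    matrix(rep(c(10, 40, 5, 2, 50), each = 101), ncol = 5))
  expect_equal(classify_outcome(tr_mix)$composition,
               "predU_preyI_dominant")
})

test_that("stochastic classification uses exact zeros at the final state", {
  # predator alive deterministically in tail mean, but absorbed at the end
  st <- matrix(rep(c(1500, 0, 6, 0, 0), each = 101), ncol = 5)
  st[101, 3] <- 0
  tr <- synthetic_trajectory(0:100, st, engine = "stochastic")
  expect_equal(classify_outcome(tr)$coexistence, "prey_only")
})

test_that("ensemble aggregation returns permutation-invariant frequencies", {
  o1 <- run_outcome(make_params(Qy = 0), "deterministic", t_max = 200)
  o2 <- run_outcome(make_params(), "deterministic", t_max = 200)
  expect_equal(unname(aggregate_ensemble(list(o1, o1, o1))), 1)
  f <- aggregate_ensemble(list(o1, o2, o1, o2))
  expect_equal(unname(f), c(0.5, 0.5))
  expect_equal(sum(f), 1)
  expect_identical(aggregate_ensemble(list(o1, o2, o2, o1)),
                   aggregate_ensemble(list(o2, o2, o1, o1)))
  expect_error(aggregate_ensemble(list()), "empty")
})

test_that("a single-cell sweep agrees with direct classification", {
  base <- make_params()
  sw <- sweep_plane(base, "Qx", 1, "Qy", 0, engine = "deterministic",
                    t_max = 500)
  expect_equal(nrow(sw), 1L)
  direct <- run_outcome(make_params(Qy = 0), "deterministic", t_max = 500)
  expect_equal(sw$label, format(direct))
  expect_equal(sw$frequency, 1)
  expect_error(sweep_plane(base, "QQ", 1, "Qy", 0), "axis")
})

test_that("stochastic sweep frequencies sum to one per cell", {
  sw <- sweep_plane(make_params(), "Qx", c(0.5, 1), "Qy", c(0.5, 1),
                    engine = "stochastic", n_reps = 4, base_seed = 7,
                    t_max = 20)
  sums <- tapply(sw$frequency, interaction(sw$Qx, sw$Qy), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("bisection locates an outcome boundary and rejects flat brackets", {
  base <- make_params()
  qy_star <- find_threshold(base, "Qy", "all_three", c(0.05, 0.9),
                            t_max = 800)
  expect_gt(qy_star, 0.15)
  expect_lt(qy_star, 0.4)
  expect_error(
    find_threshold(base, "Qy", "all_three", c(0.5, 0.9), t_max = 800),
    "differ")
})

test_that("region-edge scanning finds band-shaped regions", {
  # the predator-infected / prey-uninfected band along Qx at Qy = 1 is
  # missed by a wide two-point bracket but found by the scanning edge finder
  base <- make_params()
  edge <- find_region_edge(base, "Qx", "predI_preyU_dominant",
                           lower = 0.05, upper = 0.3, step = 0.02,
                           tol = 0.01, t_max = 1000)
  expect_false(is.na(edge))
  expect_gt(edge, 0.08)
  expect_lt(edge, 0.2)
  none <- find_region_edge(base, "Qx", "predI_preyU_dominant",
                           lower = 0.01, upper = 0.05, step = 0.02,
                           tol = 0.01, t_max = 400)
  expect_true(is.na(none))
})
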