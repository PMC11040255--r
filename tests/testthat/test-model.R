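test_that("the network has 24 state-changing channels with printed rates", {
  p <- make_params()
  net <- reaction_network(p)
  expect_length(net, 24L)
  # hand-evaluated propensity: infected prey eaten by uninfected predator,
  # successful infection with predator offspring: rp*ky*Qy*fy*xI*yU
  s <- make_state(0, 10, 5, 0, 0)
  a <- propensities(net, s, p)
  expect_equal(unname(a[["predation XI+YU infection with offspring"]]),
               1 * 0.2 * 1 * 0.01 * 10 * 5)  # = 0.1
  # total prey removal by predation equals fy * x * y
  is_predation <- grepl("^predation", names(a))
  removes_prey <- vapply(net, function(r)
    sum(r$delta[c("xU", "xI")]) < 0, logical(1))
  for (s2 in random_states(5)) {
    a2 <- propensities(net, s2, p)
    expect_equal(sum(a2[is_predation & removes_prey]),
                 p$fy * (s2[["xU"]] + s2[["xI"]]) *
                   (s2[["yU"]] + s2[["yI"]]))
  }
})

test_that("without predator infection no channel can infect or seed parasites", {
  p <- make_params(Qy = 0)
  net <- reaction_network(p)
  infects <- vapply(net, function(r)
    r$delta[["yI"]] > 0 || r$delta[["z"]] > 0, logical(1))
  for (s in random_states(5)) {
    a <- propensities(net, s, p)
    expect_true(all(a[infects] == 0))
  }
})

test_that("parasite bookkeeping follows the life cycle exactly", {
  p <- make_params()
  net <- reaction_network(p)
  dz_ <- vapply(net, function(r) r$delta[["z"]], numeric(1))
  labels <- vapply(net, `[[`, character(1), "label")
  expect_setequal(unique(dz_), c(0, -1, p$nz))
  # one parasite consumed per successful prey infection
  expect_equal(dz_[labels == "prey infection XU+Z"], -1)
  # nz released per successful predator infection, -1 on death, else 0
  expect_equal(sum(dz_ == p$nz), 4L)  # the four infection/reinfection channels
  expect_equal(sum(dz_ == -1), 2L)    # prey infection + parasite death
})

test_that("infected prey only ever produce uninfected offspring", {
  net <- reaction_network(make_params())
  births <- Filter(function(r) grepl("^prey birth", r$label), net)
  expect_length(births, 2L)
  for (r in births)
    expect_equal(r$delta, c(xU = 1, xI = 0, yU = 0, yI = 0, z = 0))
})

test_that("network drift matches the rate equations up to 1/K pair counting", {
  for (p in random_params(3, seed = 7)) {
    net <- reaction_network(p)
    for (s in random_states(7, seed = round(p$Qx * 1e4))) {
      drift <- network_drift(net, s, p)
      rhs <- ode_rhs(s, p)
      correction <- c(xU = s[["xU"]] / p$K, xI = s[["xI"]] / p$K,
                      yU = 0, yI = 0, z = 0)
      expect_lt(max(abs(drift - rhs - correction)), 1e-9)
    }
  }
})

test_that("the compiled SSA channel table equals the R network", {
  for (p in list(make_params(), make_params(Qy = 0.4, rp = 0.5, re = 0.8,
                                            rx = 0.6, nz = 3))) {
    net <- reaction_network(p)
    D_r <- t(vapply(net, function(r) r$delta, numeric(5)))
    for (s in random_states(5, seed = 11)) {
      ch <- tritroph:::ssa_channels(s, p)
      expect_equal(unname(propensities(net, s, p)), ch$propensity)
      expect_equal(unname(D_r), unname(ch$delta))
    }
  }
})

test_that("active channels never drive an abundance negative", {
  p <- make_params()
  net <- reaction_network(p)
  for (s in random_states(10, seed = 3, max_abund = 3)) {
    for (r in net) {
      if (r$rate_law(s, p) > 0)
        expect_true(all(s + r$delta >= 0),
                    label = paste("channel", r$label))
    }
  }
})
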