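# The individual-level reaction network.
#
# Every state-changing event of the model is one of 24 channels.  Reactions
# whose product equals their reactant (a failed prey infection, say) carry no
# dynamics and are not represented; their probabilities enter the remaining
# channels as multiplicative factors.  Outcomes of a predation encounter
# (offspring or not, infection or not) are exclusive channels whose rates sum
# to the total encounter rate fy * prey * predator.

#' Build the reaction network
#'
#' Returns the complete list of state-changing reaction channels of the
#' model: prey reproduction (infected parents reproduce at rate `gx * rx`
#' and always produce uninfected offspring), pairwise competition among prey
#' at rate `1/K` (same-type pairs counted as ordered pairs, `n * (n-1) / K`),
#' prey infection by free-living parasites (consuming one parasite),
#' predation for all four prey-by-predator type pairings with their
#' offspring/infection outcomes (successful trophic transmission converts
#' the predator to the infected type and releases `nz` parasite offspring),
#' and the five intrinsic death channels.
#'
#' @param p a `tri_params` object.
#' @return a list of `tri_reaction` objects, each with fields `label`,
#'   `rate_law` (a `function(state, p)` returning the propensity) and
#'   `delta` (integer change vector over `(xU, xI, yU, yI, z)`).
#' @examples
#' net <- reaction_network(make_params())
#' length(net)  # 24 channels
#' @export
reaction_network <- function(p) {
  stopifnot(inherits(p, "tri_params"))
  nz <- p$nz
  d <- function(xU = 0, xI = 0, yU = 0, yI = 0, z = 0)
    c(xU = xU, xI = xI, yU = yU, yI = yI, z = z)

  ch <- function(label, rate_law, delta)
    structure(list(label = label, rate_law = rate_law, delta = delta),
              class = "tri_reaction")

  list(
    ch("prey birth from XI",
       function(s, p) p$gx * p$rx * s[["xI"]], d(xU = +1)),
    ch("prey birth from XU",
       function(s, p) p$gx * s[["xU"]], d(xU = +1)),
    ch("competition XI,XI",
       function(s, p) s[["xI"]] * (s[["xI"]] - 1) / p$K, d(xI = -1)),
    ch("competition XI beats XU",
       function(s, p) s[["xI"]] * s[["xU"]] / p$K, d(xU = -1)),
    ch("competition XU beats XI",
       function(s, p) s[["xU"]] * s[["xI"]] / p$K, d(xI = -1)),
    ch("competition XU,XU",
       function(s, p) s[["xU"]] * (s[["xU"]] - 1) / p$K, d(xU = -1)),
    ch("prey infection XU+Z",
       function(s, p) p$Qx * p$S * s[["xU"]] * s[["z"]],
       d(xU = -1, xI = +1, z = -1)),
    ch("predation XU+YU with offspring",
       function(s, p) p$ky * p$fy * s[["xU"]] * s[["yU"]],
       d(xU = -1, yU = +1)),
    ch("predation XU+YU without offspring",
       function(s, p) (1 - p$ky) * p$fy * s[["xU"]] * s[["yU"]],
       d(xU = -1)),
    ch("predation XI+YU infection with offspring",
       function(s, p) p$rp * p$ky * p$Qy * p$fy * s[["xI"]] * s[["yU"]],
       d(xI = -1, yI = +1, z = nz)),
    ch("predation XI+YU infection without offspring",
       function(s, p) (1 - p$rp * p$ky) * p$Qy * p$fy * s[["xI"]] * s[["yU"]],
       d(xI = -1, yU = -1, yI = +1, z = nz)),
    ch("predation XI+YU exposure with offspring",
       function(s, p) p$re * p$ky * (1 - p$Qy) * p$fy * s[["xI"]] * s[["yU"]],
       d(xI = -1, yU = +1)),
    ch("predation XI+YU exposure without offspring",
       function(s, p) (1 - p$re * p$ky) * (1 - p$Qy) * p$fy *
         s[["xI"]] * s[["yU"]],
       d(xI = -1)),
    ch("predation XU+YI with offspring",
       function(s, p) p$rp * p$ky * p$fy * s[["xU"]] * s[["yI"]],
       d(xU = -1, yU = +1)),
    ch("predation XU+YI without offspring",
       function(s, p) (1 - p$rp * p$ky) * p$fy * s[["xU"]] * s[["yI"]],
       d(xU = -1)),
    ch("predation XI+YI reinfection with offspring",
       function(s, p) p$rp^2 * p$ky * p$Qy * p$fy * s[["xI"]] * s[["yI"]],
       d(xI = -1, yU = +1, z = nz)),
    ch("predation XI+YI reinfection without offspring",
       function(s, p) (1 - p$rp^2 * p$ky) * p$Qy * p$fy *
         s[["xI"]] * s[["yI"]],
       d(xI = -1, z = nz)),
    ch("predation XI+YI exposure with offspring",
       function(s, p) p$rp * p$re * p$ky * (1 - p$Qy) * p$fy *
         s[["xI"]] * s[["yI"]],
       d(xI = -1, yU = +1)),
    ch("predation XI+YI exposure without offspring",
       function(s, p) (1 - p$rp * p$re * p$ky) * (1 - p$Qy) * p$fy *
         s[["xI"]] * s[["yI"]],
       d(xI = -1)),
    ch("death XU", function(s, p) p$dx * s[["xU"]], d(xU = -1)),
    ch("death XI", function(s, p) p$dx * s[["xI"]], d(xI = -1)),
    ch("death YU", function(s, p) p$dy * s[["yU"]], d(yU = -1)),
    ch("death YI", function(s, p) p$dy * s[["yI"]], d(yI = -1)),
    ch("death Z",  function(s, p) p$dz * s[["z"]],  d(z = -1))
  )
}

#' Channel propensities at a state
#'
#' @param net a reaction network from [reaction_network()].
#' @param state a state vector (see [make_state()]).
#' @param p the `tri_params` the network was built for.
#' @return named numeric vector of propensities, one per channel.
#' @export
propensities <- function(net, state, p) {
  s <- as_state(state)
  a <- vapply(net, function(r) r$rate_law(s, p), numeric(1))
  names(a) <- vapply(net, `[[`, character(1), "label")
  a
}

#' Expected instantaneous drift of the reaction network
#'
#' The sum of `delta * propensity` over all channels: the expected rate of
#' change of each population.  It equals the deterministic right-hand side
#' [ode_rhs()] except for the same-type competition terms, where the network
#' counts ordered pairs `n * (n - 1)` while the mean-field equations use
#' `n^2` (a relative difference of order `1/K`).
#'
#' @inheritParams propensities
#' @return named numeric drift vector over `(xU, xI, yU, yI, z)`.
#' @export
network_drift <- function(net, state, p) {
  s <- as_state(state)
  drift <- c(xU = 0, xI = 0, yU = 0, yI = 0, z = 0)
  for (r in net) drift <- drift + r$delta * r$rate_law(s, p)
  drift
}

# compiled-core channel table at one state (propensity vector + delta matrix),
# used to keep the C++ SSA and the R network in lock-step
ssa_channels <- function(state, p) {
  s <- check_integer_state(as_state(state))
  .Call(C_ssa_channels, as.numeric(s), as_param_vector(p))
}
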