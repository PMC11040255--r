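# System state: abundances of the five populations.

STATE_ORDER <- c("xU", "xI", "yU", "yI", "z")

#' Create a system state
#'
#' A state holds the abundances of the five populations: uninfected prey
#' `xU`, infected prey `xI`, uninfected predators `yU`, infected predators
#' `yI` and free-living parasites `z`.  Stochastic simulation requires
#' integer counts; the deterministic equations accept any nonnegative reals.
#'
#' @param xU,xI,yU,yI,z nonnegative abundances.
#' @return a named numeric vector in the order `(xU, xI, yU, yI, z)`.
#' @examples
#' make_state()  # the reference initial condition
#' @export
make_state <- function(xU = 800, xI = 0, yU = 100, yI = 0, z = 1000) {
  s <- c(xU = as.numeric(xU), xI = as.numeric(xI), yU = as.numeric(yU),
         yI = as.numeric(yI), z = as.numeric(z))
  if (any(!is.finite(s)) || any(s < 0))
    stop("abundances must be finite and nonnegative")
  s
}

#' Reference initial condition
#'
#' 800 uninfected prey, 100 uninfected predators and 1000 free-living
#' parasites, with no infected hosts: the initial condition used throughout
#' the worked examples and parameter sweeps.
#'
#' @return a named state vector.
#' @export
reference_state <- function() make_state(800, 0, 100, 0, 1000)

as_state <- function(s) {
  if (is.null(names(s))) {
    if (length(s) != 5L) stop("a state needs 5 components")
    names(s) <- STATE_ORDER
  }
  if (!all(STATE_ORDER %in% names(s))) stop("state components missing")
  s <- s[STATE_ORDER]
  if (any(!is.finite(s)) || any(s < 0))
    stop("abundances must be finite and nonnegative")
  s
}

check_integer_state <- function(s) {
  if (any(abs(s - round(s)) > 1e-9))
    stop("stochastic simulation requires integer-valued abundances")
  round(s)
}
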