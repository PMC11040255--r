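# Model parameters and their validation.

# canonical ordering used by the compiled code
PARAM_ORDER <- c("gx", "rx", "dx", "K", "S", "Qx", "nz", "dz",
                 "fy", "ky", "Qy", "rp", "re", "dy")

# reference parameter set (all-species-coexistence example; no reproductive
# costs, both infection probabilities at their maximum)
REFERENCE_PARAMS <- list(
  gx = 2,     # prey reproduction rate
  rx = 1,     # reproductive cost factor on infected prey (1 = no cost)
  dx = 0.1,   # prey intrinsic death rate
  K  = 2000,  # prey carrying capacity (competition scales as 1/K)
  S  = 5e-4,  # prey-parasite encounter rate per pair
  Qx = 1,     # probability an encounter infects the prey
  nz = 6,     # parasite offspring per successful predator infection
  dz = 0.09,  # free-living parasite death rate
  fy = 0.01,  # predation rate per prey-predator pair
  ky = 0.2,   # predator reproduction efficiency per consumed prey
  Qy = 1,     # probability consuming infected prey infects the predator
  rp = 1,     # reproductive cost factor on infected predator (1 = no cost)
  re = 1,     # reproductive cost factor for exposure without infection
  dy = 1      # predator intrinsic death rate
)

#' Create and validate a model parameter set
#'
#' The model has fourteen rates and probabilities: prey reproduction `gx`,
#' prey death `dx` and carrying capacity `K`; prey-parasite encounter rate
#' `S` with infection probability `Qx`; predation rate `fy` with predator
#' reproduction efficiency `ky` and predator infection probability `Qy`;
#' parasite brood size `nz` and free-living death rate `dz`; predator death
#' rate `dy`; and the multiplicative reproductive cost factors `rx`
#' (infected prey), `rp` (infected predator) and `re` (predator exposed but
#' not infected), where 1 means no cost and 0 full sterilisation.  Infection
#' is assumed at least as costly as mere exposure, so `rp <= re` is enforced.
#'
#' Unspecified parameters default to the reference coexistence set
#' (`gx = 2`, `rx = 1`, `dx = 0.1`, `K = 2000`, `S = 5e-4`, `Qx = 1`,
#' `nz = 6`, `dz = 0.09`, `fy = 0.01`, `ky = 0.2`, `Qy = 1`, `rp = 1`,
#' `re = 1`, `dy = 1`).
#'
#' @param ... named parameter values, or a single named list of them.
#' @return an object of class `tri_params` (a validated named list).
#' @examples
#' p <- make_params()              # reference set
#' p2 <- make_params(Qy = 0.3, rp = 0.8)
#' @export
make_params <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1]]))
    dots <- dots[[1]]
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots)))))
    stop("all parameter values must be named")
  unknown <- setdiff(names(dots), PARAM_ORDER)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- REFERENCE_PARAMS
  p[names(dots)] <- lapply(dots, as.numeric)
  validate_params(p)
  structure(p, class = "tri_params")
}

validate_params <- function(p) {
  num1 <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", name, "' must be a single finite number")
    v
  }
  for (name in c("gx", "dx", "S", "dz", "fy", "dy"))
    if (num1(name) <= 0)
      stop("parameter '", name, "' must be strictly positive")
  for (name in c("rx", "Qx", "ky", "Qy", "rp", "re")) {
    v <- num1(name)
    if (v < 0 || v > 1)
      stop("parameter '", name, "' must lie in [0, 1]")
  }
  if (num1("K") < 1) stop("parameter 'K' must be >= 1")
  nz <- num1("nz")
  if (nz < 1 || abs(nz - round(nz)) > 1e-8)
    stop("parameter 'nz' must be a positive integer")
  if (p$rp > p$re + 1e-12)
    stop("constraint violated: rp must not exceed re ",
         "(infection at least as costly as exposure)")
  invisible(p)
}

# validated copy of `p` with the named entries replaced (used by sweeps)
update_params <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 1L && is.null(names(repl)) && is.list(repl[[1]]))
    repl <- repl[[1]]
  q <- unclass(p)
  q[names(repl)] <- lapply(repl, as.numeric)
  do.call(make_params, q)
}

as_param_vector <- function(p) {
  stopifnot(inherits(p, "tri_params"))
  unlist(p[PARAM_ORDER])
}

#' @export
print.tri_params <- function(x, ...) {
  cat("Predator-prey-parasite model parameters:\n")
  v <- unlist(x[PARAM_ORDER])
  print(v)
  invisible(x)
}

#' Read a parameter set from a flat YAML config file
#'
#' The file must contain only scalar `name: value` entries with names among
#' the fourteen model parameters; unknown keys are an error.  Missing
#' parameters take their reference defaults.
#'
#' @param path path to a YAML file.
#' @return a validated `tri_params` object.
#' @seealso [write_params()], [make_params()]
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a flat name: value mapping")
  make_params(vals)
}

#' Write a parameter set to a flat YAML config file
#'
#' @param p a `tri_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "tri_params"))
  yaml::write_yaml(p[PARAM_ORDER], path)
  invisible(path)
}
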