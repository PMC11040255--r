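# Trajectory and sweep serialisation: tidy CSV plus a JSON sidecar.

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds the columns `t, xU, xI, yU, yI, z`; the sidecar
#' (`<path>.json`) records the parameters, engine, seed and termination
#' status.  Integer stochastic states round-trip bit-exactly.
#'
#' @param traj a `tri_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tri_trajectory"))
  df <- as.data.frame(traj)
  df$t <- sprintf("%.17g", df$t)  # full double precision for event times
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(engine = attr(traj, "engine"),
               seed = attr(traj, "seed"),
               terminated = attr(traj, "terminated"),
               params = unclass(attr(traj, "params"))[PARAM_ORDER])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the sidecar `<path>.json` must exist).
#' @return a `tri_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  seed <- meta$seed
  new_trajectory(df$t, as.matrix(df[STATE_ORDER]),
                 engine = meta$engine,
                 params = make_params(as.list(meta$params)),
                 seed = if (is.null(seed) || is.na(seed)) NA_integer_
                        else as.integer(seed),
                 terminated = meta$terminated)
}

#' Write a sweep result to CSV with a JSON metadata sidecar
#'
#' @param sweep a data frame from [sweep_plane()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  meta <- attr(sweep, "meta")
  if (!is.null(meta)) {
    meta$base <- unclass(meta$base)[PARAM_ORDER]
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
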