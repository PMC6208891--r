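#' Covariate trajectory on a uniform time grid
#'
#' Container for a covariate (e.g. 1-D position) sampled at every time step of
#' the simulation/observation grid. Step `t` covers the interval
#' `((t-1)*dt, t*dt]` and carries the value `values[t]`.
#'
#' @param values numeric vector of covariate values, one per time step.
#' @param dt time-step size in time units per step (default 1, i.e. times are
#'   measured in steps).
#' @return An object of class `covariate_trajectory` with fields `values`,
#'   `dt`, `n_steps`.
#' @examples
#' x <- covariate_trajectory(sin(seq_len(100) / 10))
#' x$n_steps
#' @export
covariate_trajectory <- function(values, dt = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("covariate needs at least one step")
  if (!all(is.finite(values))) stop("covariate values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  structure(
    list(values = values, dt = dt, n_steps = length(values)),
    class = "covariate_trajectory"
  )
}

#' @export
print.covariate_trajectory <- function(x, ...) {
  cat(sprintf(
    "Covariate trajectory: %d steps, dt = %g, range [%.3g, %.3g]\n",
    x$n_steps, x$dt, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Read / write a covariate trajectory as CSV
#'
#' Two-column CSV with header `time_step,value`; `time_step` is the 1-based
#' grid index.
#'
#' @param x a `covariate_trajectory`.
#' @param path file path.
#' @param dt step size to attach on read.
#' @return `read_covariate_csv` returns a `covariate_trajectory`;
#'   `write_covariate_csv` returns `path` invisibly.
#' @export
write_covariate_csv <- function(x, path) {
  stopifnot(inherits(x, "covariate_trajectory"))
  utils::write.csv(
    data.frame(time_step = seq_len(x$n_steps), value = x$values),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_covariate_csv
#' @export
read_covariate_csv <- function(path, dt = 1) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_step", "value") %in% names(df))) {
    stop("covariate CSV must have columns 'time_step' and 'value'")
  }
  covariate_trajectory(df$value[order(df$time_step)], dt = dt)
}
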