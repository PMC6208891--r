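#' Marked spike train
#'
#' Ordered spike (event) times on an observation interval `[0, T]`, each
#' carrying a d-dimensional mark vector (e.g. waveform peak amplitudes), and
#' optionally a generating-neuron label used by history-dependent models whose
#' history kernels act on per-neuron spike sets.
#'
#' @param times strictly increasing numeric vector of spike times in time-step
#'   units, all in `[0, T]`. Ties are rejected; callers that need to break ties
#'   must jitter explicitly (by less than `dt / 10`).
#' @param marks numeric vector (1-D marks) or matrix with one row per spike.
#' @param T end of the observation interval (time-step units).
#' @param dt grid step size.
#' @param neuron optional integer vector of generating-component labels.
#' @return An object of class `marked_train`.
#' @examples
#' tr <- marked_train(c(10, 25, 40), c(11.2, 11.9, 10.8), T = 100)
#' n_spikes(tr)
#' @export
marked_train <- function(times, marks, T, dt = 1, neuron = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(marks))) marks <- matrix(as.numeric(marks), ncol = 1L)
  marks <- as.matrix(marks)
  storage.mode(marks) <- "double"
  dimnames(marks) <- NULL
  n <- length(times)
  if (n > 0 && nrow(marks) != n) stop("marks must have one row per spike")
  if (any(!is.finite(times)) || (n > 0 && any(!is.finite(marks)))) {
    stop("times and marks must be finite")
  }
  if (n > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing (ties are rejected; ",
         "jitter explicitly by < dt/10 if needed)")
  }
  if (!is.finite(T) || T <= 0) stop("T must be positive")
  if (n > 0 && (times[1] < 0 || times[n] > T)) {
    stop("spike times must lie in [0, T]")
  }
  if (!is.null(neuron)) {
    neuron <- as.integer(neuron)
    if (length(neuron) != n) stop("neuron labels must have one entry per spike")
  }
  structure(
    list(times = times, marks = marks, T = T, dt = dt, neuron = neuron),
    class = "marked_train"
  )
}

#' @rdname marked_train
#' @param x a `marked_train`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "marked_train"))
  length(x$times)
}

#' @export
print.marked_train <- function(x, ...) {
  cat(sprintf(
    "Marked spike train: %d spikes on [0, %g], mark dimension %d%s\n",
    n_spikes(x), x$T, ncol(x$marks),
    if (is.null(x$neuron)) "" else ", with neuron labels"
  ))
  invisible(x)
}

#' Read / write marked spike trains as CSV
#'
#' Header `time,mark_1,...,mark_d` (plus optional `neuron`); times in
#' time-step units.
#'
#' @param x a `marked_train`.
#' @param path file path.
#' @param T,dt interval end and step size to attach on read; `T = NULL` uses
#'   the last spike time rounded up to the next step.
#' @export
write_marked_train <- function(x, path) {
  stopifnot(inherits(x, "marked_train"))
  d <- ncol(x$marks)
  df <- data.frame(time = x$times)
  for (k in seq_len(d)) df[[paste0("mark_", k)]] <- x$marks[, k]
  if (!is.null(x$neuron)) df$neuron <- x$neuron
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marked_train
#' @export
read_marked_train <- function(path, T = NULL, dt = 1) {
  if (!file.exists(path)) stop("train file not found: ", path)
  df <- utils::read.csv(path)
  mark_cols <- grep("^mark_[0-9]+$", names(df), value = TRUE)
  if (!("time" %in% names(df)) || length(mark_cols) == 0) {
    stop("train CSV must have columns 'time' and 'mark_1', ..., 'mark_d'")
  }
  mark_cols <- mark_cols[order(as.integer(sub("^mark_", "", mark_cols)))]
  if (is.null(T)) T <- if (nrow(df) > 0) ceiling(max(df$time) / dt) * dt else dt
  marked_train(df$time, as.matrix(df[, mark_cols, drop = FALSE]),
               T = T, dt = dt,
               neuron = if ("neuron" %in% names(df)) df$neuron else NULL)
}

#' Mark-space integration grid
#'
#' Quadrature support over a model's mark domain: a dense uniform grid for
#' mark dimension d <= 2, or a seeded quasi-uniform Monte-Carlo sample for
#' d >= 3, where a dense product grid is impractical. For models with a
#' discrete mark space (sorted-unit models) the grid is the set of atoms with
#' unit counting weight.
#'
#' @param domain d x 2 matrix of per-dimension closed interval bounds (or a
#'   length-2 vector for d = 1).
#' @param n number of nodes per dimension (d <= 2) or total Monte-Carlo points
#'   (d >= 3; default 20000).
#' @param seed seed for the Monte-Carlo sample (d >= 3 only).
#' @return An object of class `mark_grid` with fields `points` (n x d matrix),
#'   `weights` (quadrature weight per point), `domain`, `measure` (total mark
#'   domain measure), `discrete`.
#' @export
mark_grid <- function(domain, n = NULL, seed = 1L) {
  if (is.null(dim(domain))) domain <- matrix(domain, ncol = 2L)
  domain <- as.matrix(domain)
  if (ncol(domain) != 2 || any(domain[, 2] <= domain[, 1])) {
    stop("domain must be a d x 2 matrix of nonempty intervals")
  }
  d <- nrow(domain)
  widths <- domain[, 2] - domain[, 1]
  measure <- prod(widths)
  if (d <= 2) {
    if (is.null(n)) n <- if (d == 1) 512L else 101L
    axes <- lapply(seq_len(d), function(k) {
      # cell-centered nodes so weights sum exactly to the domain measure
      h <- widths[k] / n
      domain[k, 1] + h * (seq_len(n) - 0.5)
    })
    pts <- as.matrix(expand.grid(axes))
    dimnames(pts) <- NULL
    w <- rep(measure / nrow(pts), nrow(pts))
  } else {
    if (is.null(n)) n <- 20000L
    pts <- with_seed(seed, vapply(seq_len(d), function(k) {
      # scrambled stratified sample per axis: quasi-uniform but seeded
      u <- (seq_len(n) - stats::runif(n)) / n
      domain[k, 1] + widths[k] * sample(u)
    }, numeric(n)))
    w <- rep(measure / n, n)
  }
  structure(
    list(points = pts, weights = w, domain = domain,
         measure = measure, discrete = FALSE),
    class = "mark_grid"
  )
}

#' @rdname mark_grid
#' @param atoms vector of discrete mark atoms (e.g. cluster labels).
#' @export
discrete_mark_grid <- function(atoms) {
  atoms <- as.numeric(atoms)
  structure(
    list(points = matrix(atoms, ncol = 1L), weights = rep(1, length(atoms)),
         domain = matrix(range(atoms), ncol = 2L),
         measure = length(atoms), discrete = TRUE),
    class = "mark_grid"
  )
}
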