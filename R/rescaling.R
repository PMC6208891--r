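#' Univariate time-rescaling
#'
#' Rescales event times by the cumulative integral of a conditional intensity
#' given on the simulation grid: \eqn{u_j = \int_0^{s_j} \lambda(t|H_t) dt}.
#' Under the correct model the \eqn{u_j} are a unit-rate Poisson process.
#' Integration is a left-Riemann sum over grid cells (cell `t` covers
#' `((t-1) dt, t dt]` and carries `intensity[t]`), with the partial cell up
#' to each event time included.
#'
#' @param times event times in `[0, n_steps * dt]`.
#' @param intensity nonnegative per-step intensity values.
#' @param dt grid step size.
#' @return numeric vector of rescaled times, nondecreasing with `times`.
#' @examples
#' rescale_univariate(c(0.5, 1.5), rep(2, 3), dt = 1)  # 1.0, 3.0
#' @export
rescale_univariate <- function(times, intensity, dt = 1) {
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensity must be finite and nonnegative")
  }
  if (length(times) == 0) return(numeric(0))
  if (any(times < 0) || any(times > length(intensity) * dt)) {
    stop("times must lie within [0, n_steps * dt]")
  }
  cum <- c(0, cumsum(intensity) * dt)
  k <- pmin(length(intensity), pmax(1L, ceiling(times / dt)))
  frac <- times - (k - 1) * dt
  cum[k] + intensity[k] * frac
}

# Per-component cumulative time integrals of a component set at query times,
# left-Riemann with partial final cell. Returns length(times) x C matrix.
component_cumulative <- function(comp, times) {
  n <- comp$n_steps; dt <- comp$dt
  cumM <- apply(comp$time, 2L, cumsum) * dt
  cumM <- rbind(0, matrix(cumM, nrow = n))
  k <- pmin(n, pmax(1L, ceiling(times / dt)))
  frac <- times - (k - 1) * dt
  cumM[k, , drop = FALSE] + comp$time[k, , drop = FALSE] * frac
}

#' Generalized (marked) time-rescaling
#'
#' Applies the marked point-process time-rescaling transform under a
#' candidate joint mark intensity model: each spike is rescaled along its own
#' mark, \eqn{\tau_j = \int_0^{s_j} \lambda(t, m_j|H_t) dt}, conditioning on
#' the full observed history; the observation-interval end is rescaled into
#' the mark-dependent boundary \eqn{b(m) = \int_0^T \lambda(t, m|H_t) dt};
#' and the stochastic region \eqn{R = \{(\tau, m): 0 \le \tau \le b(m)\}} has
#' volume \eqn{|R| = \int b(m) dm} accumulated by quadrature on the mark
#' grid. Under the correct model the rescaled spikes are independently
#' uniform on `R` and their count is Poisson with mean `|R|`.
#'
#' @param train a [marked_train()]; its marks must lie in the model's domain.
#' @param model a joint mark intensity model.
#' @param grid a [mark_grid()] covering the model's mark domain (default:
#'   [default_mark_grid()]).
#' @return An object of class `rescaled_pattern`: `tau` (rescaled times, in
#'   spike order), `marks`, `b_spikes` (boundary evaluated exactly at each
#'   spike's mark), `grid`, `b_grid` (boundary at the grid points),
#'   `region_volume`, `n`, `discrete`.
#' @examples
#' mod <- jmi_constant(2, c(0, 1), n_steps = 10)
#' tr <- marked_train(c(2, 5), c(0.3, 0.7), T = 10)
#' p <- rescale_marked(tr, mod)
#' p$tau            # 4, 10
#' p$region_volume  # 2 * 10
#' @export
rescale_marked <- function(train, model, grid = NULL) {
  stopifnot(inherits(train, "marked_train"), inherits(model, "jmi"))
  if (is.null(grid)) grid <- default_mark_grid(model)
  marks <- train$marks
  if (inherits(model, "sorted_pair_model")) {
    if (!grid$discrete) grid <- discrete_mark_grid(1:2)
    if (!all(marks[, 1] %in% c(1, 2))) {
      marks <- matrix(as.numeric(sort_labels(model, train$marks)), ncol = 1L)
    }
  } else {
    check_mark_domain(model, marks)
    lo <- apply(grid$points, 2, min); hi <- apply(grid$points, 2, max)
    if (n_spikes(train) > 0) {
      for (k in seq_len(ncol(marks))) {
        # allow half a grid cell beyond the outermost cell-centered node
        pad <- if (grid$discrete) 0 else (hi[k] - lo[k]) / nrow(grid$points)
        if (any(marks[, k] < lo[k] - pad | marks[, k] > hi[k] + pad)) {
          stop("observed mark outside the mark grid")
        }
      }
    }
  }
  comp <- jmi_components(model, history = train)
  if (any(comp$time < 0)) stop("negative intensity under the candidate model")
  B <- colSums(comp$time) * comp$dt          # per-component \int_0^T A_c dt
  phi_grid <- comp$markfun(grid$points)
  b_grid <- as.numeric(phi_grid %*% B)
  region_volume <- sum(grid$weights * b_grid)
  n <- n_spikes(train)
  if (n > 0) {
    phi_sp <- comp$markfun(marks)
    cum_sp <- component_cumulative(comp, train$times)
    tau <- rowSums(cum_sp * phi_sp)
    b_spikes <- as.numeric(phi_sp %*% B)
  } else {
    tau <- numeric(0); b_spikes <- numeric(0)
  }
  structure(
    list(tau = tau, marks = marks, b_spikes = b_spikes,
         grid = grid, b_grid = b_grid, region_volume = region_volume,
         n = n, T_obs = train$T, dt = comp$dt,
         discrete = isTRUE(comp$discrete)),
    class = "rescaled_pattern"
  )
}

#' @export
print.rescaled_pattern <- function(x, ...) {
  cat(sprintf(
    "Rescaled pattern: %d spikes, |R| = %.4g, max boundary %.4g%s\n",
    x$n, x$region_volume, max(x$b_grid),
    if (x$discrete) " (discrete marks)" else ""
  ))
  invisible(x)
}

#' Superposed ground intensity of a rescaled pattern
#'
#' After rescaling, the spike times (marks ignored) form an inhomogeneous
#' Poisson process with intensity
#' \eqn{\tilde\lambda(\tau) = \int I\{b(m) \ge \tau\} dm}, the mark measure
#' of the part of the region above \eqn{\tau}. Evaluated by counting grid
#' points on a uniform `tau` grid from 0 to the boundary maximum.
#'
#' @param pattern a `rescaled_pattern`.
#' @param n_tau number of `tau` grid nodes.
#' @return object of class `rescaled_ground` with fields `tau`, `lambda`,
#'   `max_b`.
#' @export
superposed_intensity <- function(pattern, n_tau = 513L) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  if (length(pattern$b_grid) == 0) stop("pattern has an empty boundary")
  max_b <- max(pattern$b_grid)
  tau <- seq(0, max_b, length.out = n_tau)
  lam <- vapply(tau, function(z) {
    sum(pattern$grid$weights[pattern$b_grid >= z])
  }, numeric(1))
  structure(list(tau = tau, lambda = lam, max_b = max_b),
            class = "rescaled_ground")
}

# Exact integral \int_0^z \tilde\lambda(s) ds = sum_i w_i min(b_i, z),
# using the grid representation of the boundary directly.
ground_cumulative <- function(pattern, z) {
  w <- pattern$grid$weights; b <- pattern$b_grid
  vapply(z, function(zi) sum(w * pmin(b, zi)), numeric(1))
}

#' Second rescaling of the superposed process
#'
#' Sorts the rescaled spike times (superposition over marks) and rescales
#' them once more by the cumulative superposed ground intensity,
#' \eqn{u_j = \int_0^{\tau_{(j)}} \tilde\lambda(\tau) d\tau}. Under the
#' correct model the `u_j` are a unit-rate Poisson process, so successive
#' differences are Exp(1).
#'
#' @param pattern a `rescaled_pattern`.
#' @param ground optional `rescaled_ground` from [superposed_intensity()];
#'   must describe the same pattern (used for validation only — the integral
#'   itself is computed exactly from the boundary).
#' @return nondecreasing numeric vector of second-rescaled times.
#' @export
second_rescale <- function(pattern, ground = NULL) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  if (!is.null(ground)) {
    if (abs(ground$max_b - max(pattern$b_grid)) >
        1e-8 * max(1, ground$max_b)) {
      stop("ground intensity does not match this pattern (different max b)")
    }
  }
  ground_cumulative(pattern, sort(pattern$tau))
}

#' Boundary-normalized rescaled times
#'
#' Divides each rescaled spike time by the boundary at the spike's own mark:
#' \eqn{\tilde\tau_j = \tau_j / b(m_j) \in [0, 1]}. Under the correct model
#' the sorted superposition of the \eqn{\tilde\tau_j} is a homogeneous
#' Poisson process on `[0, 1]` with rate equal to the observed spike count.
#'
#' @param pattern a `rescaled_pattern`.
#' @param tol boundary values at or below `tol` raise a degenerate-boundary
#'   error naming the offending spike.
#' @return numeric vector of normalized times in `[0, 1]`, in spike order.
#' @export
normalize_boundary <- function(pattern, tol = 1e-12) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  bad <- which(pattern$b_spikes <= tol)
  if (length(bad)) {
    stop(sprintf(
      "degenerate boundary b(m) <= %g at spike %d (mark %.4g)",
      tol, bad[1], pattern$marks[bad[1], 1]
    ))
  }
  pmin(1, pattern$tau / pattern$b_spikes)
}

#' Restrict a rescaled pattern to a mark subspace
#'
#' Keeps the spikes whose marks lie in a per-dimension interval subset and
#' computes the subspace ground intensity
#' \eqn{\lambda_s(\tau) = \int_{subset} I\{b(m) \ge \tau\} dm}. Under the
#' correct model the kept rescaled times are an inhomogeneous Poisson
#' process with rate \eqn{\lambda_s}.
#'
#' @param pattern a `rescaled_pattern`.
#' @param mark_subset d x 2 matrix (or length-2 vector) of interval bounds.
#' @return list with elements `pattern` (the sub-pattern, a
#'   `rescaled_pattern` whose grid and region volume are restricted to the
#'   subset) and `ground` (a `rescaled_ground` for the subspace).
#' @export
restrict_subspace <- function(pattern, mark_subset) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  if (is.null(dim(mark_subset))) mark_subset <- matrix(mark_subset, ncol = 2L)
  mark_subset <- as.matrix(mark_subset)
  pts <- pattern$grid$points
  if (ncol(pts) != nrow(mark_subset)) {
    stop("mark_subset must have one interval per mark dimension")
  }
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nrow(mark_subset))) {
    inside <- inside & pts[, k] >= mark_subset[k, 1] &
      pts[, k] <= mark_subset[k, 2]
  }
  if (!any(inside)) stop("mark_subset does not intersect the mark domain")
  keep <- rep(TRUE, pattern$n)
  if (pattern$n > 0) {
    for (k in seq_len(nrow(mark_subset))) {
      keep <- keep & pattern$marks[, k] >= mark_subset[k, 1] &
        pattern$marks[, k] <= mark_subset[k, 2]
    }
  }
  sub_grid <- pattern$grid
  sub_grid$points <- pts[inside, , drop = FALSE]
  sub_grid$weights <- pattern$grid$weights[inside]
  sub_grid$measure <- sum(sub_grid$weights)
  sub <- structure(
    list(tau = pattern$tau[keep],
         marks = pattern$marks[keep, , drop = FALSE],
         b_spikes = pattern$b_spikes[keep],
         grid = sub_grid, b_grid = pattern$b_grid[inside],
         region_volume = sum(sub_grid$weights * pattern$b_grid[inside]),
         n = sum(keep), T_obs = pattern$T_obs, dt = pattern$dt,
         discrete = pattern$discrete),
    class = "rescaled_pattern"
  )
  list(pattern = sub, ground = superposed_intensity(sub))
}

#' Write / read a rescaled pattern
#'
#' CSV with columns `tau,mark_1,...,mark_d` plus a JSON sidecar
#' (`<path>.json`) holding the boundary samples, grid weights and region
#' volume.
#'
#' @param pattern a `rescaled_pattern`.
#' @param path CSV path; the sidecar is written next to it (and read back
#'   from there by `read_rescaled_pattern`).
#' @export
write_rescaled_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  d <- ncol(pattern$marks)
  df <- data.frame(tau = pattern$tau)
  for (k in seq_len(d)) df[[paste0("mark_", k)]] <- pattern$marks[, k]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(b_grid = pattern$b_grid, grid_points = pattern$grid$points,
         grid_weights = pattern$grid$weights,
         region_volume = pattern$region_volume,
         b_spikes = pattern$b_spikes, T_obs = pattern$T_obs,
         dt = pattern$dt, discrete = pattern$discrete),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rescaled_pattern
#' @export
read_rescaled_pattern <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mark_cols <- grep("^mark_[0-9]+$", names(df), value = TRUE)
  mark_cols <- mark_cols[order(as.integer(sub("^mark_", "", mark_cols)))]
  marks <- as.matrix(df[, mark_cols, drop = FALSE])
  dimnames(marks) <- NULL
  pts <- matrix(unlist(side$grid_points), nrow = length(side$grid_weights))
  grid <- structure(
    list(points = pts, weights = as.numeric(side$grid_weights),
         domain = cbind(apply(pts, 2, min), apply(pts, 2, max)),
         measure = sum(side$grid_weights),
         discrete = isTRUE(side$discrete)),
    class = "mark_grid"
  )
  structure(
    list(tau = df$tau, marks = marks,
         b_spikes = as.numeric(side$b_spikes), grid = grid,
         b_grid = as.numeric(side$b_grid),
         region_volume = side$region_volume,
         n = nrow(df), T_obs = side$T_obs, dt = side$dt,
         discrete = isTRUE(side$discrete)),
    class = "rescaled_pattern"
  )
}
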