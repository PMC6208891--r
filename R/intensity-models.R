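#' Joint mark intensity models
#'
#' A joint mark intensity \eqn{\lambda(t, m | H_t)} gives the instantaneous
#' rate of observing a spike with mark \eqn{m} at time \eqn{t}, given the
#' spiking history \eqn{H_t}; integrating it over the mark space yields the
#' ground intensity \eqn{\Lambda(t|H_t)}. Every concrete family implemented
#' here is a finite sum of components, each a (history-dependent) time factor
#' multiplied by a mark factor,
#' \deqn{\lambda(t, m|H_t) = \sum_c A_c(t|H_t)\, \phi_c(m),}
#' which the package exploits: integrals over marks reduce to analytic
#' Gaussian masses, and integrals over time to cumulative sums of the
#' \eqn{A_c} on the simulation grid.
#'
#' Families:
#' \itemize{
#'   \item `jmi_constant()` — a constant rate, for tests and examples.
#'   \item `place_field_model()` — two place cells with Gaussian spatial
#'     tuning and Gaussian 1-D mark distributions; optional refractory
#'     history kernels for both neurons and a lagged excitatory kernel from
#'     neuron 2 onto neuron 1.
#'   \item `sorted_pair_model()` — the crudely spike-sorted variant: marks
#'     become discrete cluster labels via an amplitude threshold and the
#'     history kernels act on the threshold-sorted spike sets.
#'   \item `mog_model()` — clusterless mixture-of-Gaussians intensity over
#'     joint (position, mark) space with d-dimensional marks.
#'   \item `kernel_model()` — clusterless kernel (KB) intensity estimator
#'     built from training spikes with an occupancy-normalized denominator.
#' }
#'
#' Intensities carry units of spikes per time step per unit mark measure
#' (mark factors of Gaussian families are normalized densities).
#'
#' @name intensity-models
NULL

# ---- internal component contract --------------------------------------------
# jmi_components(model, history) returns:
#   time        n_steps x C matrix of nonnegative time factors A_c(t|H_t)
#   markfun     function(M: n x d matrix) -> n x C matrix of mark factors
#   mass        length-C vector of full-domain mark-factor integrals
#   dt, n_steps, d, mark_domain (d x 2), discrete
jmi_components <- function(model, history = NULL) {
  UseMethod("jmi_components")
}

apply_scaling <- function(model, comp) {
  g <- model$scale_global %||% 1
  if (g != 1) comp$time <- comp$time * g
  sc <- model$scale_components
  if (!is.null(sc)) {
    if (length(sc) != ncol(comp$time)) {
      stop("component_factors length must match the number of components")
    }
    comp$time <- sweep(comp$time, 2L, sc, `*`)
  }
  comp
}

check_jmi_params <- function(p) {
  bad <- names(p)[!vapply(p, function(v) all(is.finite(v)), logical(1))]
  if (length(bad)) stop("non-finite model parameter(s): ",
                        paste(bad, collapse = ", "))
  invisible(p)
}

#' Number of additive components of a model
#' @param model a joint mark intensity model.
#' @export
n_components <- function(model) UseMethod("n_components")

#' @export
n_components.jmi <- function(model) model$n_components

# ---- constant model ---------------------------------------------------------

#' @rdname intensity-models
#' @param rate intensity value in spikes per step per unit mark: a scalar
#'   for a constant model, or a length-`n_steps` vector for a
#'   mark-independent time-varying rate.
#' @param mark_domain d x 2 matrix (or length-2 vector) of mark bounds.
#' @param n_steps number of grid steps of the observation interval.
#' @param dt step size.
#' @export
jmi_constant <- function(rate, mark_domain = c(0, 1), n_steps = 100L, dt = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be finite and >= 0")
  }
  if (length(rate) > 1 && length(rate) != n_steps) {
    stop("a rate vector must have one value per step")
  }
  if (is.null(dim(mark_domain))) mark_domain <- matrix(mark_domain, ncol = 2L)
  structure(
    list(rate = rate, mark_domain = as.matrix(mark_domain),
         n_steps = as.integer(n_steps), dt = dt,
         d = nrow(as.matrix(mark_domain)),
         n_components = 1L, requires_history = FALSE),
    class = c("jmi_constant", "jmi")
  )
}

#' @export
jmi_components.jmi_constant <- function(model, history = NULL) {
  measure <- prod(model$mark_domain[, 2] - model$mark_domain[, 1])
  comp <- list(
    time = matrix(rep_len(model$rate, model$n_steps), model$n_steps, 1L),
    markfun = function(M) matrix(1, nrow(M), 1L),
    mass = measure,
    dt = model$dt, n_steps = model$n_steps, d = model$d,
    mark_domain = model$mark_domain, discrete = FALSE
  )
  apply_scaling(model, comp)
}

# ---- place-field population model -------------------------------------------

#' Default parameters of the two-neuron place-field population
#'
#' Peak place-field rates of 0.15 spikes per time step (`a1`, `a2` on the log
#' scale), place-field centers at -2 and +2 with width sqrt(0.5), Gaussian
#' mark distributions centered at 11 and 12 with sd 0.3, excitatory gain
#' exp(`a3`) = 0.3 at lag `r` = 10 steps with kernel width `sigma_1` = 2
#' steps, and refractory kernel width `sigma_2` = 14 steps.
#'
#' @return named list of model parameters.
#' @export
study1_params <- function() {
  list(
    a1 = log(0.15), a2 = log(0.15), a3 = log(0.3),
    mu_x1 = -2, mu_x2 = 2, sigma_x1 = sqrt(0.5), sigma_x2 = sqrt(0.5),
    mu_m1 = 11, mu_m2 = 12, sigma_m1 = 0.3, sigma_m2 = 0.3,
    sigma_1 = 2, sigma_2 = 14, r = 10
  )
}

validate_pfp_params <- function(p) {
  need <- names(study1_params())
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  check_jmi_params(p[need])
  sig <- c("sigma_x1", "sigma_x2", "sigma_m1", "sigma_m2", "sigma_1", "sigma_2")
  if (any(unlist(p[sig]) <= 0)) stop("all sigma parameters must be > 0")
  if (p$r < 0) stop("excitatory lag r must be >= 0")
  p[need]
}

#' @rdname intensity-models
#' @param params named parameter list, see [study1_params()].
#' @param covariate a [covariate_trajectory()] driving the place fields.
#' @param history_enabled if `FALSE` the refractory/excitatory kernels are
#'   dropped and the model is a pure place-by-mark inhomogeneous Poisson
#'   population.
#' @export
place_field_model <- function(params = study1_params(), covariate,
                              history_enabled = TRUE) {
  stopifnot(inherits(covariate, "covariate_trajectory"))
  params <- validate_pfp_params(params)
  span <- 6 * max(params$sigma_m1, params$sigma_m2)
  dom <- matrix(c(min(params$mu_m1, params$mu_m2) - span,
                  max(params$mu_m1, params$mu_m2) + span), ncol = 2L)
  structure(
    list(params = params, covariate = covariate,
         history_enabled = isTRUE(history_enabled),
         mark_domain = dom, d = 1L,
         n_steps = covariate$n_steps, dt = covariate$dt,
         n_components = 2L, requires_history = isTRUE(history_enabled)),
    class = c("pfp_model", "jmi")
  )
}

# Refractory log-factor and excitatory additive term over grid steps 1..n for
# a given spike set (times in step units). Kernels are effectively local, so
# each spike only touches a + 6 sigma window of steps after it. The same
# single-spike appliers drive the incremental simulator state, keeping the
# simulated and rescaled quadrature conventions identical.
pfp_refr_window <- function(si, n_steps, p) {
  t0 <- floor(si) + 1L
  if (t0 > n_steps) return(NULL)
  t1 <- min(n_steps, t0 + ceiling(6 * p$sigma_2))
  dl <- (t0:t1) - si
  list(idx = t0:t1, add = log(pmax(1 - exp(-dl^2 / (2 * p$sigma_2^2)),
                                   1e-300)))
}

pfp_excit_window <- function(si, n_steps, p) {
  t0 <- floor(si) + 1L
  if (t0 > n_steps) return(NULL)
  t1 <- min(n_steps, t0 + ceiling(p$r + 6 * p$sigma_1))
  dl <- (t0:t1) - si
  list(idx = t0:t1, add = exp(p$a3 - (dl - p$r)^2 / (2 * p$sigma_1^2)))
}

pfp_history_terms <- function(s1, s2, n_steps, p) {
  logH1 <- numeric(n_steps); logH2 <- numeric(n_steps); E1 <- numeric(n_steps)
  for (si in s1) {
    w <- pfp_refr_window(si, n_steps, p)
    if (!is.null(w)) logH1[w$idx] <- logH1[w$idx] + w$add
  }
  for (si in s2) {
    w <- pfp_refr_window(si, n_steps, p)
    if (!is.null(w)) logH2[w$idx] <- logH2[w$idx] + w$add
    we <- pfp_excit_window(si, n_steps, p)
    if (!is.null(we)) E1[we$idx] <- E1[we$idx] + we$add
  }
  list(logH1 = logH1, logH2 = logH2, E1 = E1)
}

split_history_pfp <- function(model, history) {
  if (is.null(history) || n_spikes(history) == 0) {
    return(list(s1 = numeric(0), s2 = numeric(0)))
  }
  stopifnot(inherits(history, "marked_train"))
  if (is.null(history$neuron)) {
    stop("the place-field population model's history kernels act on ",
         "per-neuron spike sets: supply a train with neuron labels")
  }
  s <- history$times / history$dt
  list(s1 = s[history$neuron == 1L], s2 = s[history$neuron == 2L])
}

pfp_time_factors <- function(model, s1, s2) {
  p <- model$params
  x <- model$covariate$values
  lx1 <- exp(p$a1 - (x - p$mu_x1)^2 / (2 * p$sigma_x1^2))
  lx2 <- exp(p$a2 - (x - p$mu_x2)^2 / (2 * p$sigma_x2^2))
  if (model$history_enabled && (length(s1) + length(s2)) > 0) {
    h <- pfp_history_terms(s1, s2, model$n_steps, p)
    cbind((lx1 + h$E1) * exp(h$logH1), lx2 * exp(h$logH2))
  } else {
    cbind(lx1, lx2)
  }
}

#' @export
jmi_components.pfp_model <- function(model, history = NULL) {
  p <- model$params
  hs <- if (model$history_enabled) split_history_pfp(model, history)
        else list(s1 = numeric(0), s2 = numeric(0))
  comp <- list(
    time = pfp_time_factors(model, hs$s1, hs$s2),
    markfun = function(M) cbind(stats::dnorm(M[, 1], p$mu_m1, p$sigma_m1),
                                stats::dnorm(M[, 1], p$mu_m2, p$sigma_m2)),
    mass = c(1, 1),  # full-line Gaussian mark masses
    dt = model$dt, n_steps = model$n_steps, d = 1L,
    mark_domain = model$mark_domain, discrete = FALSE
  )
  apply_scaling(model, comp)
}

# ---- crudely sorted pair model ----------------------------------------------

#' @rdname intensity-models
#' @param sort_threshold amplitude cutoff: spikes with first mark at or below
#'   it are assigned to cluster 1, above it to cluster 2.
#' @export
sorted_pair_model <- function(params = study1_params(), covariate,
                              sort_threshold = 11.5) {
  stopifnot(inherits(covariate, "covariate_trajectory"))
  params <- validate_pfp_params(params)
  if (!is.finite(sort_threshold)) stop("sort_threshold must be finite")
  structure(
    list(params = params, covariate = covariate,
         sort_threshold = sort_threshold,
         history_enabled = TRUE,
         mark_domain = matrix(c(1, 2), ncol = 2L), d = 1L,
         n_steps = covariate$n_steps, dt = covariate$dt,
         n_components = 2L, requires_history = TRUE),
    class = c("sorted_pair_model", "jmi")
  )
}

#' Classify continuous marks into the sorted model's cluster labels
#' @param model a `sorted_pair_model`.
#' @param marks mark matrix or vector.
#' @return integer labels (1 = at/below threshold, 2 = above).
#' @export
sort_labels <- function(model, marks) {
  m1 <- if (is.null(dim(marks))) as.numeric(marks) else marks[, 1]
  ifelse(m1 > model$sort_threshold, 2L, 1L)
}

#' @export
jmi_components.sorted_pair_model <- function(model, history = NULL) {
  if (is.null(history) || n_spikes(history) == 0) {
    s1 <- numeric(0); s2 <- numeric(0)
  } else {
    lab <- sort_labels(model, history$marks)
    s <- history$times / history$dt
    s1 <- s[lab == 1L]; s2 <- s[lab == 2L]
  }
  comp <- list(
    time = pfp_time_factors(model, s1, s2),
    # discrete mark space {1, 2} with counting measure
    markfun = function(M) cbind(as.numeric(M[, 1] == 1),
                                as.numeric(M[, 1] == 2)),
    mass = c(1, 1),
    dt = model$dt, n_steps = model$n_steps, d = 1L,
    mark_domain = model$mark_domain, discrete = TRUE
  )
  apply_scaling(model, comp)
}

# ---- mixture of Gaussians ----------------------------------------------------

#' @rdname intensity-models
#' @param lambda length-M vector of component peak rates (>= 0).
#' @param f,sigma2 length-M position centers and variances.
#' @param mu M x d matrix of component mark means.
#' @param Sigma list of M symmetric positive-definite d x d mark matrices,
#'   applied directly in the quadratic form
#'   \eqn{\exp[-(m-\mu_c)^\top \Sigma_c (m-\mu_c)/2]} (precision-like).
#' @export
mog_model <- function(lambda, f, sigma2, mu, Sigma, covariate,
                      mark_domain = NULL) {
  stopifnot(inherits(covariate, "covariate_trajectory"))
  mu <- as.matrix(mu)
  M <- length(lambda); d <- ncol(mu)
  if (length(f) != M || length(sigma2) != M || nrow(mu) != M ||
      length(Sigma) != M) {
    stop("lambda, f, sigma2, mu, Sigma must all describe M components")
  }
  check_jmi_params(list(lambda = lambda, f = f, sigma2 = sigma2, mu = mu,
                        Sigma = unlist(Sigma)))
  if (any(lambda < 0)) stop("component rates lambda must be >= 0")
  if (any(sigma2 <= 0)) stop("position variances must be > 0")
  covs <- lapply(Sigma, function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("each Sigma_c must be symmetric")
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("each Sigma_c must be positive definite")
    solve(S)  # covariance implied by the precision-like quadratic form
  })
  if (is.null(mark_domain)) {
    sds <- t(vapply(covs, function(C) sqrt(diag(C)), numeric(d)))
    mark_domain <- cbind(apply(mu - 6 * sds, 2, min),
                         apply(mu + 6 * sds, 2, max))
  }
  structure(
    list(lambda = as.numeric(lambda), f = as.numeric(f),
         sigma2 = as.numeric(sigma2), mu = mu, Sigma = lapply(Sigma, as.matrix),
         covariate = covariate, mark_domain = as.matrix(mark_domain), d = d,
         n_steps = covariate$n_steps, dt = covariate$dt,
         n_components = M, requires_history = FALSE),
    class = c("mog_model", "jmi")
  )
}

#' @export
jmi_components.mog_model <- function(model, history = NULL) {
  x <- model$covariate$values
  time <- vapply(seq_len(model$n_components), function(c) {
    model$lambda[c] * exp(-(x - model$f[c])^2 / (2 * model$sigma2[c]))
  }, numeric(model$n_steps))
  time <- matrix(time, nrow = model$n_steps)
  mu <- model$mu; Sig <- model$Sigma; d <- model$d
  markfun <- function(M) {
    out <- matrix(0, nrow(M), length(Sig))
    for (c in seq_along(Sig)) {
      dev <- sweep(M, 2L, mu[c, ], `-`)
      out[, c] <- exp(-0.5 * rowSums((dev %*% Sig[[c]]) * dev))
    }
    out
  }
  mass <- vapply(Sig, function(S) (2 * pi)^(d / 2) / sqrt(det(S)), numeric(1))
  comp <- list(time = time, markfun = markfun, mass = mass,
               dt = model$dt, n_steps = model$n_steps, d = d,
               mark_domain = model$mark_domain, discrete = FALSE)
  apply_scaling(model, comp)
}

# ---- kernel-based (KB) estimator --------------------------------------------

#' @rdname intensity-models
#' @param spike_x positions at the N training spikes.
#' @param marks N x K matrix of training-spike marks.
#' @param occupancy_x positions of the T occupancy time bins entering the
#'   denominator (defaults to the evaluation covariate's values).
#' @param Bx,Bm,bx Gaussian bandwidths for spike position, mark (isotropic
#'   over the K mark dimensions), and occupancy.
#' @param denom_floor lower floor applied to the occupancy denominator; bins
#'   that underflow it are floored with a warning.
#' @export
kernel_model <- function(spike_x, marks, covariate, occupancy_x = NULL,
                         Bx, Bm, bx, denom_floor = 1e-12) {
  stopifnot(inherits(covariate, "covariate_trajectory"))
  marks <- as.matrix(marks)
  N <- length(spike_x)
  if (N < 1) stop("kernel model needs at least one training spike")
  if (nrow(marks) != N) stop("marks must have one row per training spike")
  if (any(c(Bx, Bm, bx) <= 0)) stop("all bandwidths must be > 0")
  occupancy_x <- occupancy_x %||% covariate$values
  K <- ncol(marks)
  span <- 6 * max(Bm, apply(marks, 2, stats::sd), na.rm = TRUE)
  dom <- cbind(apply(marks, 2, min) - span, apply(marks, 2, max) + span)
  structure(
    list(spike_x = as.numeric(spike_x), marks = marks,
         occupancy_x = as.numeric(occupancy_x), covariate = covariate,
         Bx = Bx, Bm = Bm, bx = bx, denom_floor = denom_floor,
         mark_domain = dom, d = K,
         n_steps = covariate$n_steps, dt = covariate$dt,
         n_components = N, requires_history = FALSE),
    class = c("kernel_model", "jmi")
  )
}

kb_denominator <- function(model) {
  x <- model$covariate$values
  occ <- model$occupancy_x
  D <- numeric(length(x))
  # chunked occupancy sum keeps memory bounded for long trajectories
  chunk <- max(1L, floor(5e6 / length(occ)))
  for (i0 in seq(1L, length(x), by = chunk)) {
    idx <- i0:min(length(x), i0 + chunk - 1L)
    D[idx] <- rowSums(stats::dnorm(outer(x[idx], occ, `-`), sd = model$bx))
  }
  D <- model$dt * D
  if (any(D < model$denom_floor)) {
    warning("occupancy denominator floored at ", model$denom_floor,
            " in ", sum(D < model$denom_floor), " bins")
    D <- pmax(D, model$denom_floor)
  }
  D
}

#' @export
jmi_components.kernel_model <- function(model, history = NULL) {
  x <- model$covariate$values
  D <- kb_denominator(model)
  time <- stats::dnorm(outer(x, model$spike_x, `-`), sd = model$Bx) / D
  Bm <- model$Bm; mk <- model$marks; K <- model$d
  markfun <- function(M) {
    out <- matrix(0, nrow(M), nrow(mk))
    for (n in seq_len(nrow(mk))) {
      dev <- sweep(M, 2L, mk[n, ], `-`)
      out[, n] <- (2 * pi * Bm^2)^(-K / 2) *
        exp(-rowSums(dev^2) / (2 * Bm^2))
    }
    out
  }
  comp <- list(time = time, markfun = markfun, mass = rep(1, nrow(mk)),
               dt = model$dt, n_steps = model$n_steps, d = K,
               mark_domain = model$mark_domain, discrete = FALSE)
  apply_scaling(model, comp)
}

# ---- generic operations ------------------------------------------------------

#' Evaluate a joint mark intensity
#'
#' Returns \eqn{\lambda(t, m | H_t)} at grid time `t` (time-step units) and
#' mark `m`, conditioning on the spikes of `history` strictly before `t`.
#'
#' @param model a joint mark intensity model.
#' @param t evaluation time in `(0, T]`, time-step units; the covariate value
#'   of the grid cell containing `t` is used.
#' @param m mark vector (or matrix of marks, one per row). For discrete-mark
#'   models `m` is a cluster label.
#' @param history optional [marked_train()] of prior spikes; spikes at or
#'   after `t` are excluded.
#' @return nonnegative intensity value(s).
#' @examples
#' cov <- covariate_trajectory(rep(-2, 10))
#' mod <- place_field_model(study1_params(), cov, history_enabled = FALSE)
#' evaluate_jmi(mod, t = 5, m = 11)
#' @export
evaluate_jmi <- function(model, t, m, history = NULL) {
  stopifnot(inherits(model, "jmi"))
  if (t <= 0 || t > model$n_steps * model$dt) stop("t outside the time grid")
  m <- as_mark_matrix(m, model$d)
  if (!isTRUE(attr(model, "skip_domain_check"))) check_mark_domain(model, m)
  if (!is.null(history) && n_spikes(history) > 0) {
    keep <- history$times < t
    history <- marked_train(history$times[keep],
                            history$marks[keep, , drop = FALSE],
                            T = history$T, dt = history$dt,
                            neuron = history$neuron[keep])
  }
  comp <- jmi_components(model, history)
  step <- min(comp$n_steps, max(1L, ceiling(t / comp$dt)))
  as.numeric(comp$markfun(m) %*% comp$time[step, ])
}

check_mark_domain <- function(model, m) {
  dom <- model$mark_domain
  if (inherits(model, "sorted_pair_model")) {
    if (!all(m[, 1] %in% c(1, 2))) {
      stop("mark outside domain: sorted model marks are cluster labels 1/2")
    }
    return(invisible(TRUE))
  }
  for (k in seq_len(nrow(dom))) {
    if (any(m[, k] < dom[k, 1] | m[, k] > dom[k, 2])) {
      stop(sprintf("mark outside domain in dimension %d ([%g, %g])",
                   k, dom[k, 1], dom[k, 2]))
    }
  }
  invisible(TRUE)
}

#' Ground intensity (mark-integrated conditional intensity)
#'
#' \eqn{\Lambda(t|H_t) = \int \lambda(t, m|H_t)\, dm} over the mark domain.
#' Gaussian-mark families use exact analytic masses; `method = "quadrature"`
#' integrates numerically on a mark grid instead.
#'
#' @inheritParams evaluate_jmi
#' @param method `"analytic"` (exact component mark masses) or
#'   `"quadrature"` (sum over `grid`).
#' @param grid a [mark_grid()]; required for `method = "quadrature"`.
#' @return nonnegative rate (spikes per time unit).
#' @export
ground_intensity <- function(model, t, history = NULL,
                             method = c("analytic", "quadrature"),
                             grid = NULL) {
  stopifnot(inherits(model, "jmi"))
  method <- match.arg(method)
  if (t <= 0 || t > model$n_steps * model$dt) stop("t outside the time grid")
  comp <- jmi_components(model, history)
  step <- min(comp$n_steps, max(1L, ceiling(t / comp$dt)))
  if (method == "analytic") {
    sum(comp$time[step, ] * comp$mass)
  } else {
    if (is.null(grid) || nrow(grid$points) == 0) {
      stop("quadrature requires a nonempty mark_grid")
    }
    phi <- comp$markfun(grid$points)
    sum((phi %*% comp$time[step, ]) * grid$weights)
  }
}

#' Scale a joint mark intensity model
#'
#' Multiplies the intensity everywhere by `global_factor` and/or multiplies
#' each additive component's intensity by the corresponding entry of
#' `component_factors` (equivalently a shift of that component's log peak
#' rate).
#'
#' @param model a joint mark intensity model.
#' @param global_factor positive scalar.
#' @param component_factors optional positive vector, one per component.
#' @return a model of the same family.
#' @export
scale_model <- function(model, global_factor = 1, component_factors = NULL) {
  stopifnot(inherits(model, "jmi"))
  if (!is.finite(global_factor) || global_factor <= 0) {
    stop("global_factor must be positive")
  }
  if (!is.null(component_factors)) {
    if (length(component_factors) != n_components(model)) {
      stop("component_factors length must match the number of components")
    }
    if (any(!is.finite(component_factors) | component_factors <= 0)) {
      stop("component_factors must be positive")
    }
    model$scale_components <-
      (model$scale_components %||% rep(1, n_components(model))) *
      component_factors
  }
  model$scale_global <- (model$scale_global %||% 1) * global_factor
  model
}

#' Default mark grid for a model
#'
#' Dense cell-centered grid for mark dimension <= 2, seeded Monte-Carlo
#' sample for higher dimensions, discrete atoms for sorted-unit models.
#'
#' @param model a joint mark intensity model.
#' @param n nodes per dimension (d <= 2) or Monte-Carlo points (d >= 3).
#' @param seed seed for the Monte-Carlo sample.
#' @export
default_mark_grid <- function(model, n = NULL, seed = 1L) {
  stopifnot(inherits(model, "jmi"))
  if (inherits(model, "sorted_pair_model")) return(discrete_mark_grid(1:2))
  mark_grid(model$mark_domain, n = n, seed = seed)
}

#' @export
print.jmi <- function(x, ...) {
  cat(sprintf(
    "Joint mark intensity model <%s>: %d component(s), mark dimension %d,\n  %d grid steps (dt = %g)%s\n",
    class(x)[1], n_components(x), x$d, x$n_steps, x$dt,
    if (isTRUE(x$requires_history)) ", history-dependent" else ""
  ))
  invisible(x)
}
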