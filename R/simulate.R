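#' Simulate an AR(1) covariate trajectory
#'
#' \eqn{x_t = \alpha x_{t-1} + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \sigma^2)}, \eqn{x_0} drawn from the stationary
#' distribution \eqn{N(0, \sigma^2/(1-\alpha^2))}.
#'
#' @param alpha autoregressive coefficient, `|alpha| < 1`.
#' @param sigma innovation standard deviation (> 0).
#' @param n_steps trajectory length.
#' @param seed RNG seed (identical seeds give identical trajectories).
#' @param dt step size attached to the trajectory.
#' @return a [covariate_trajectory()].
#' @export
simulate_ar1 <- function(alpha = 0.98, sigma = 0.3, n_steps = 10000L,
                         seed = 1L, dt = 1) {
  if (!is.finite(alpha) || abs(alpha) >= 1) {
    stop("|alpha| must be < 1 for stationarity")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  x <- with_seed(seed, {
    x0 <- stats::rnorm(1, 0, sigma / sqrt(1 - alpha^2))
    eps <- stats::rnorm(n_steps, 0, sigma)
    as.numeric(stats::filter(eps, alpha, method = "recursive", init = x0))
  })
  covariate_trajectory(x, dt = dt)
}

# Sample `n` accepted (tau, mark) points uniformly under the boundary
# b(m) = sum_c B[c] phi_c(m) by rejection from the rectangular envelope
# [0, b_max] x mark domain.
sample_region <- function(comp, B, b_max, n, min_acceptance = 1e-4) {
  dom <- comp$mark_domain
  d <- nrow(dom)
  taus <- numeric(0); mks <- matrix(0, 0, d)
  proposed <- 0; accepted <- 0
  acc_est <- 0.33  # refined from observed acceptance after the first batch
  while (accepted < n) {
    if (proposed > 0) acc_est <- max(accepted / proposed, 1e-3)
    batch <- max(200L, ceiling(1.3 * (n - accepted) / acc_est))
    batch <- min(batch, 200000L)
    m <- vapply(seq_len(d), function(k) {
      stats::runif(batch, dom[k, 1], dom[k, 2])
    }, numeric(batch))
    m <- matrix(m, ncol = d)
    tau <- stats::runif(batch, 0, b_max)
    b_m <- as.numeric(comp$markfun(m) %*% B)
    ok <- tau <= b_m
    proposed <- proposed + batch
    accepted <- accepted + sum(ok)
    taus <- c(taus, tau[ok])
    mks <- rbind(mks, m[ok, , drop = FALSE])
    if (proposed >= 1e6 && accepted / proposed < min_acceptance) {
      stop("rejection acceptance rate below ", min_acceptance,
           "; consider a tighter mark domain for the envelope")
    }
  }
  list(tau = taus[seq_len(n)], marks = mks[seq_len(n), , drop = FALSE])
}

# Invert rescaled times along each point's own mark: smallest grid step t
# with sum_c cumM[t + 1, c] * phi[i, c] >= target_i (ties toward the earlier
# step). Vectorized binary search; returns step indices.
invert_times <- function(cumM, phi, target, lo_step = 1L) {
  n_steps <- nrow(cumM) - 1L
  np <- length(target)
  lo <- rep(as.integer(lo_step), np); hi <- rep(n_steps, np)
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    val <- rowSums(cumM[mid + 1L, , drop = FALSE] * phi)
    ge <- val >= target
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge] + 1L
  }
  lo
}

# Separate duplicated grid-step spike times by deterministic backward
# sub-cell offsets (total spread < dt/10), keeping the train strictly
# increasing and inside [0, T]: inverted times sit at the right edge of
# their grid cell, so ties are spread backward into the cell.
dejitter_ties <- function(times, dt) {
  o <- order(times)
  t_sorted <- times[o]
  if (anyDuplicated(t_sorted)) {
    run <- stats::ave(seq_along(t_sorted), t_sorted, FUN = seq_along)
    size <- stats::ave(seq_along(t_sorted), t_sorted, FUN = length)
    t_sorted <- t_sorted - (size - run) * dt / (10 * size)
  }
  t_sorted
}

#' Simulate a marked point process without history dependence
#'
#' Implements the exact scheme for a deterministic joint mark intensity:
#' draw the total spike count from Poisson(\eqn{|R|}) with
#' \eqn{|R| = \int\int \lambda(t, m) dt\, dm}; sample each spike uniformly
#' in the region under the boundary \eqn{b(m)} by rejection from a
#' rectangular envelope; and invert each rescaled time along its own mark,
#' \eqn{s_i = \min\{s : \tau_i = \int_0^s \lambda(t, m_i) dt\}}, resolved to
#' the earliest grid step. Spikes landing on the same grid step are
#' separated by a deterministic sub-cell offset (< dt/100 per tie) so the
#' returned train is strictly increasing.
#'
#' @param model a history-free joint mark intensity model.
#' @param grid a [mark_grid()] (default: the model's default grid).
#' @param seed RNG seed.
#' @param T horizon; defaults to the model's full grid extent and must not
#'   exceed it.
#' @return a [marked_train()] with generating-component labels in `$neuron`.
#' @export
simulate_marked <- function(model, grid = NULL, seed = 1L, T = NULL) {
  stopifnot(inherits(model, "jmi"))
  if (isTRUE(model$requires_history)) {
    stop("model depends on history; use simulate_marked_history()")
  }
  if (is.null(grid)) grid <- default_mark_grid(model)
  comp <- jmi_components(model, NULL)
  T <- T %||% (comp$n_steps * comp$dt)
  n_T <- floor(T / comp$dt + 1e-9)
  if (n_T < 1 || n_T > comp$n_steps) stop("T outside the model's time grid")
  if (n_T < comp$n_steps) {
    comp$time <- comp$time[seq_len(n_T), , drop = FALSE]
    comp$n_steps <- n_T
  }
  B <- colSums(comp$time) * comp$dt
  b_grid <- as.numeric(comp$markfun(grid$points) %*% B)
  R_vol <- sum(grid$weights * b_grid)
  if (!is.finite(R_vol)) stop("total integrated intensity is not finite")
  with_seed(seed, {
    N <- stats::rpois(1, R_vol)
    if (N == 0) {
      return(marked_train(numeric(0), matrix(0, 0, comp$d), T = T,
                          dt = comp$dt, neuron = integer(0)))
    }
    pts <- sample_region(comp, B, max(b_grid), N)
    cumM <- rbind(0, apply(comp$time, 2L, cumsum) * comp$dt)
    cumM <- matrix(cumM, ncol = ncol(comp$time))
    phi <- comp$markfun(pts$marks)
    steps <- invert_times(cumM, phi, pts$tau)
    lab <- sample_labels(comp, steps, phi)
    o <- order(steps, pts$tau)
    times <- dejitter_ties(steps[o] * comp$dt, comp$dt)
    marked_train(times, pts$marks[o, , drop = FALSE], T = T, dt = comp$dt,
                 neuron = lab[o])
  })
}

# Draw a generating-component label for each spike, proportional to the
# component's share of intensity at the spike's (step, mark).
sample_labels <- function(comp, steps, phi) {
  w <- comp$time[steps, , drop = FALSE] * phi
  vapply(seq_len(nrow(w)), function(i) {
    wi <- w[i, ]
    if (sum(wi) <= 0) wi <- rep(1, length(wi))
    sample.int(length(wi), 1L, prob = wi)
  }, integer(1))
}

#' Simulate a history-dependent marked point process
#'
#' Iterative scheme: starting from an empty history, simulate a full set of
#' spikes forward from the current frontier under the intensity conditioned
#' on the accepted history, fix the earliest new spike, update the
#' intensity, and repeat from that spike's time, stopping when a forward
#' Poisson draw returns zero spikes or the horizon is exhausted. Previously
#' accepted spikes are never un-fixed.
#'
# Incremental simulator state: sim_accept() must update comp$time to the
# intensity conditioned on the history including the newly fixed spike.
# The default rebuilds the components from scratch; the place-field family
# applies its (local) history kernels incrementally.
sim_accept <- function(model, comp, spike, history) UseMethod("sim_accept")

#' @export
sim_accept.jmi <- function(model, comp, spike, history) {
  n_T <- comp$n_steps
  full <- jmi_components(model, history)
  if (n_T < full$n_steps) {
    full$time <- full$time[seq_len(n_T), , drop = FALSE]
    full$n_steps <- n_T
  }
  comp$time <- full$time
  comp
}

#' @export
sim_accept.pfp_model <- function(model, comp, spike, history) {
  pfp_sim_accept(model, comp, spike, group = spike$label)
}

#' @export
sim_accept.sorted_pair_model <- function(model, comp, spike, history) {
  pfp_sim_accept(model, comp, spike,
                 group = sort_labels(model, matrix(spike$mark, nrow = 1L)))
}

pfp_sim_accept <- function(model, comp, spike, group) {
  if (!isTRUE(model$history_enabled)) return(comp)
  p <- model$params
  st <- comp$sim_state
  n_T <- comp$n_steps
  si <- spike$time / comp$dt
  touched <- integer(0)
  w <- pfp_refr_window(si, n_T, p)
  if (!is.null(w)) {
    if (group == 1L) st$logH1[w$idx] <- st$logH1[w$idx] + w$add
    else st$logH2[w$idx] <- st$logH2[w$idx] + w$add
    touched <- w$idx
  }
  if (group == 2L) {
    we <- pfp_excit_window(si, n_T, p)
    if (!is.null(we)) {
      st$E1[we$idx] <- st$E1[we$idx] + we$add
      touched <- union(touched, we$idx)
    }
  }
  if (length(touched)) {
    g <- model$scale_global %||% 1
    sc <- model$scale_components %||% c(1, 1)
    comp$time[touched, 1] <- g * sc[1] *
      (st$lx1[touched] + st$E1[touched]) * exp(st$logH1[touched])
    comp$time[touched, 2] <- g * sc[2] *
      st$lx2[touched] * exp(st$logH2[touched])
  }
  comp$sim_state <- st
  comp
}

#' @inheritParams simulate_marked
#' @param model a joint mark intensity model (may depend on history).
#' @param max_iterations cap on the accept-one-spike loop.
#' @return a [marked_train()] with generating-component labels.
#' @export
simulate_marked_history <- function(model, grid = NULL, seed = 1L, T = NULL,
                                    max_iterations = 100000L) {
  stopifnot(inherits(model, "jmi"))
  if (max_iterations < 1) stop("max_iterations must be positive")
  if (is.null(grid)) grid <- default_mark_grid(model)
  comp <- jmi_components(model, NULL)
  T <- T %||% (comp$n_steps * comp$dt)
  n_T <- floor(T / comp$dt + 1e-9)
  if (n_T < 1 || n_T > comp$n_steps) stop("T outside the model's time grid")
  if (n_T < comp$n_steps) {
    comp$time <- comp$time[seq_len(n_T), , drop = FALSE]
    comp$n_steps <- n_T
  }
  dt <- comp$dt
  if (inherits(model, "pfp_model") || inherits(model, "sorted_pair_model")) {
    p <- model$params
    x <- model$covariate$values[seq_len(n_T)]
    comp$sim_state <- list(
      lx1 = exp(p$a1 - (x - p$mu_x1)^2 / (2 * p$sigma_x1^2)),
      lx2 = exp(p$a2 - (x - p$mu_x2)^2 / (2 * p$sigma_x2^2)),
      E1 = numeric(n_T), logH1 = numeric(n_T), logH2 = numeric(n_T)
    )
  }
  phi_grid <- comp$markfun(grid$points)
  seeds <- sub_seeds(seed, max_iterations + 1L)
  times <- numeric(0); marks <- matrix(0, 0, comp$d); labels <- integer(0)
  t_front <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iterations) {
      stop(sprintf(
        "iterative simulation did not terminate within %d iterations (%d spikes accepted, frontier at t = %.6g)",
        max_iterations, length(times), t_front
      ))
    }
    if (any(comp$time < 0)) stop("negative intensity during simulation")
    cumM <- rbind(0, apply(comp$time, 2L, cumsum) * dt)
    cumM <- matrix(cumM, ncol = ncol(comp$time))
    cum_front <- if (t_front > 0) {
      k <- min(n_T, max(1L, ceiling(t_front / dt)))
      cumM[k, ] + comp$time[k, ] * (t_front - (k - 1) * dt)
    } else rep(0, ncol(comp$time))
    B_win <- pmax(cumM[n_T + 1L, ] - cum_front, 0)
    b_grid <- as.numeric(phi_grid %*% B_win)
    R_win <- sum(grid$weights * b_grid)
    if (!is.finite(R_win)) stop("total integrated intensity is not finite")
    new_spike <- with_seed(seeds[iter], {
      N <- stats::rpois(1, R_win)
      if (N == 0) NULL else {
        pts <- sample_region(comp, B_win, max(b_grid), N)
        phi <- comp$markfun(pts$marks)
        target <- pts$tau + as.numeric(phi %*% cum_front)
        steps <- invert_times(cumM, phi, target,
                              lo_step = max(1L, ceiling(t_front / dt)))
        j <- which.min(steps + pts$tau * 1e-12)
        lab <- sample_labels(comp, steps[j], phi[j, , drop = FALSE])
        list(time = steps[j] * dt, mark = pts$marks[j, ], label = lab)
      }
    })
    if (is.null(new_spike)) break
    s_new <- new_spike$time
    if (length(times) && s_new <= times[length(times)]) {
      s_new <- times[length(times)] + dt / 100  # collision: re-jitter
    }
    if (s_new > T) break
    times <- c(times, s_new)
    marks <- rbind(marks, new_spike$mark)
    labels <- c(labels, new_spike$label)
    t_front <- s_new
    new_spike$time <- s_new
    history <- marked_train(times, marks, T = T, dt = dt, neuron = labels)
    comp <- sim_accept(model, comp, new_spike, history)
  }
  marked_train(times, marks, T = T, dt = dt, neuron = labels)
}

#' Synthetic tetrode-style clusterless fixture
#'
#' Builds a seeded mixture-of-Gaussians joint mark intensity with
#' 4-dimensional amplitude-like marks over an AR(1) position trajectory —
#' place-specific firing with multi-channel mark clusters plus, when
#' `hash_fraction > 0`, a broad low-amplitude "hash" component emulating
#' threshold-crossing events that are not attributable to well-isolated
#' units — and simulates a marked spike train from it. Both the train and
#' the generating model are returned so rescaling under the truth can be
#' checked.
#'
#' @param seed RNG seed (fixed seed gives an identical fixture).
#' @param n_components number of place-coding mark clusters (>= 1),
#'   excluding the hash component.
#' @param hash_fraction expected fraction of spikes from the hash component,
#'   in `[0, 1)`.
#' @param n_steps trajectory length.
#' @param expected_spikes approximate expected total spike count.
#' @return list with elements `train` (a [marked_train()]) and `model` (the
#'   generating [mog_model()]).
#' @export
make_tetrode_fixture <- function(seed = 1L, n_components = 3L,
                                 hash_fraction = 0.2, n_steps = 3000L,
                                 expected_spikes = 300) {
  if (n_components < 1) stop("n_components must be >= 1")
  if (hash_fraction < 0 || hash_fraction >= 1) {
    stop("hash_fraction must lie in [0, 1)")
  }
  seeds <- sub_seeds(seed, 3L)
  cov <- simulate_ar1(0.98, 0.3, n_steps, seed = seeds[1])
  d <- 4L
  par <- with_seed(seeds[2], {
    f <- stats::runif(n_components, -2, 2)
    mu <- matrix(stats::runif(n_components * d, 3.5, 6.5), ncol = d)
    list(f = f, mu = mu)
  })
  sigma2 <- rep(0.4, n_components)
  Sigma <- replicate(n_components, diag(1 / 0.35^2, d), simplify = FALSE)
  f <- par$f; mu <- par$mu; lambda <- rep(1, n_components)
  if (hash_fraction > 0) {
    f <- c(f, 0); sigma2 <- c(sigma2, 4)  # hash fires everywhere
    mu <- rbind(mu, rep(1.5, d))
    Sigma <- c(Sigma, list(diag(1 / 0.9^2, d)))
    lambda <- c(lambda, 1)
  }
  model <- mog_model(lambda, f, sigma2, mu, Sigma, cov)
  # calibrate component rates: expected count per component at lambda_c = 1,
  # then scale so the hash share and the total match the requested values
  comp <- jmi_components(model, NULL)
  e_c <- colSums(comp$time) * comp$dt * comp$mass
  M <- n_components
  w <- rep((1 - hash_fraction) / M, M)
  if (hash_fraction > 0) w <- c(w, hash_fraction)
  model$lambda <- as.numeric(expected_spikes * w / e_c)
  train <- simulate_marked(model, seed = seeds[3])
  list(train = train, model = model)
}
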