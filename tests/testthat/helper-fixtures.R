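# Shared fixtures, built in code at test time.

# A short constant covariate pinning the position at a place-field center.
fixed_covariate <- function(x = -2, n_steps = 100L, dt = 1) {
  covariate_trajectory(rep(x, n_steps), dt = dt)
}

# History-free two-neuron model over a seeded AR(1) trajectory.
small_pf_model <- function(n_steps = 3000L, seed = 1L,
                           history_enabled = FALSE) {
  cov <- simulate_ar1(0.98, 0.3, n_steps, seed = seed)
  place_field_model(study1_params(), cov, history_enabled = history_enabled)
}

# Hand-built rescaled pattern with an arbitrary boundary over marks [0, 1],
# bypassing any model: used to test the region operations against
# closed-form oracles.
synthetic_pattern <- function(b_fun, tau, marks, n_grid = 2000L) {
  h <- 1 / n_grid
  pts <- matrix(h * (seq_len(n_grid) - 0.5), ncol = 1L)
  b_grid <- b_fun(pts[, 1])
  grid <- structure(
    list(points = pts, weights = rep(h, n_grid),
         domain = matrix(c(0, 1), ncol = 2L), measure = 1,
         discrete = FALSE),
    class = "mark_grid"
  )
  marks <- matrix(marks, ncol = 1L)
  structure(
    list(tau = tau, marks = marks, b_spikes = b_fun(marks[, 1]),
         grid = grid, b_grid = b_grid,
         region_volume = sum(grid$weights * b_grid),
         n = length(tau), T_obs = 1, dt = 1, discrete = FALSE),
    class = "rescaled_pattern"
  )
}

# Small two-component mixture model with d-dimensional marks.
small_mog <- function(d = 2L, seed = 3L, n_steps = 2000L) {
  cov <- simulate_ar1(0.98, 0.3, n_steps, seed = seed)
  mog_model(
    lambda = c(0.08, 0.08), f = c(-1.5, 1.5), sigma2 = c(0.4, 0.4),
    mu = rbind(rep(4, d), rep(6, d)),
    Sigma = list(diag(1 / 0.25, d), diag(1 / 0.25, d)),
    covariate = cov
  )
}
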