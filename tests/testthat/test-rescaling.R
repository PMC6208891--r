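test_that("univariate rescaling reproduces analytic integrals", {
  # unit intensity: identity
  expect_equal(rescale_univariate(c(1, 2.5, 7), rep(1, 10)), c(1, 2.5, 7))
  # constant intensity 2: linear scaling
  expect_equal(rescale_univariate(1.5, rep(2, 5)), 3.0)
  # lambda(t) = t on [0, 2]: int_0^2 t dt = 2, left-Riemann on a fine grid
  dt <- 2 / 1000
  lam <- (seq_len(1000) - 1) * dt
  expect_lt(abs(rescale_univariate(2, lam, dt = dt) - 2) / 2, 0.005)
  expect_error(rescale_univariate(1, c(1, -1)), "nonnegative")
})

test_that("marked rescaling: unit and linear intensities, time-varying oracle", {
  tr <- marked_train(c(2, 5), c(0.3, 0.7), T = 10)
  p1 <- rescale_marked(tr, jmi_constant(1, c(0, 1), n_steps = 10))
  expect_equal(p1$tau, c(2, 5))
  expect_equal(unique(round(p1$b_grid, 12)), 10)
  expect_equal(p1$region_volume, 10)
  p2 <- rescale_marked(tr, jmi_constant(2, c(0, 1), n_steps = 10))
  expect_equal(p2$tau, c(4, 10))
  expect_equal(p2$region_volume, 20)
  # lambda(t, m) = t (mark-independent) on [0,1] x [0,1]: spike at s = 0.5
  # has tau = 0.125, b = 0.5, |R| = 0.5
  n <- 2000L; dt <- 1 / n
  mod <- jmi_constant((seq_len(n) - 1) * dt, c(0, 1), n_steps = n, dt = dt)
  pt <- rescale_marked(marked_train(0.5, 0.4, T = 1, dt = dt), mod)
  expect_lt(abs(pt$tau - 0.125), 1e-3)
  expect_lt(abs(pt$b_grid[1] - 0.5), 1e-3)
  expect_lt(abs(pt$region_volume - 0.5), 1e-3)
})

test_that("rescaling preserves counts, containment, and monotonicity", {
  mod <- small_pf_model(n_steps = 2000, seed = 8)
  tr <- simulate_marked(mod, seed = 9)
  pat <- rescale_marked(tr, mod)
  expect_equal(pat$n, n_spikes(tr))
  expect_equal(length(pat$tau), n_spikes(tr))
  # containment with one grid cell of intensity-mass tolerance
  tol <- mod$dt * max(pat$b_grid) / 2000
  expect_true(all(pat$tau <= pat$b_spikes + tol))
  # tau is nondecreasing in s for a fixed mark
  m_fix <- 11.5
  taus <- vapply(c(100, 500, 900, 1500), function(s) {
    rescale_marked(marked_train(s, m_fix, T = 2000), mod)$tau
  }, numeric(1))
  expect_true(all(diff(taus) >= 0))
  expect_error(
    rescale_marked(marked_train(5, 100, T = 2000), mod),
    "outside"
  )
})

test_that("halving dt changes rescaled times by less than 1 percent", {
  n <- 500L
  x <- sin(seq_len(n) / 40)
  p <- study1_params(); p$mu_x1 <- -0.5; p$mu_x2 <- 0.5
  m1 <- place_field_model(p, covariate_trajectory(x, dt = 1),
                          history_enabled = FALSE)
  x2 <- rep(x, each = 2)
  m2 <- place_field_model(p, covariate_trajectory(x2, dt = 0.5),
                          history_enabled = FALSE)
  times <- c(100.5, 250, 400.25)
  tr <- marked_train(times, c(11, 11.5, 12), T = n)
  t1 <- rescale_marked(tr, m1)$tau
  t2 <- rescale_marked(tr, m2)$tau
  expect_true(all(abs(t1 - t2) / pmax(t1, 1e-12) < 0.01))
})

test_that("superposed intensity matches counting oracles", {
  # rectangular region: b = c over marks [0,1]
  rect <- synthetic_pattern(function(m) rep(2.5, length(m)),
                            tau = c(0.5, 2), marks = c(0.2, 0.8))
  g <- superposed_intensity(rect)
  expect_equal(g$lambda[1], 1)              # lambda(0) = mark measure
  expect_true(all(abs(g$lambda[g$tau <= 2.5] - 1) < 1e-9))
  # triangular boundary b(m) = m: lambda(tau) = 1 - tau within a grid cell
  tri <- synthetic_pattern(function(m) m, tau = 0.3, marks = 0.9)
  gt <- superposed_intensity(tri)
  expect_true(all(abs(gt$lambda - (1 - gt$tau)) < 1 / 1000))
  expect_true(all(diff(gt$lambda) <= 1e-12))  # nonincreasing
})

test_that("second rescaling integrates the superposed intensity exactly", {
  # rectangular region, mark measure 1: u = tau
  rect <- synthetic_pattern(function(m) rep(3, length(m)),
                            tau = c(0.4, 1.1, 2.2), marks = c(0.1, 0.5, 0.9))
  expect_equal(second_rescale(rect), c(0.4, 1.1, 2.2), tolerance = 1e-9)
  # mark measure 3 scales u by 3: emulate with b = const over [0,1] but
  # weights tripled
  rect3 <- rect; rect3$grid$weights <- rect3$grid$weights * 3
  expect_equal(second_rescale(rect3), 3 * c(0.4, 1.1, 2.2),
               tolerance = 1e-9)
  # triangular boundary, tau = 0.5: u = int_0^0.5 (1 - z) dz = 0.375
  tri <- synthetic_pattern(function(m) m, tau = 0.5, marks = 0.99)
  expect_equal(second_rescale(tri), 0.375, tolerance = 1e-3)
  # mismatched ground errors
  other <- superposed_intensity(synthetic_pattern(
    function(m) rep(99, length(m)), tau = 1, marks = 0.5))
  expect_error(second_rescale(rect, other), "does not match")
})

test_that("boundary normalization maps spikes into [0, 1]", {
  pat <- synthetic_pattern(function(m) rep(2, length(m)),
                           tau = c(0, 1, 2), marks = c(0.1, 0.5, 0.9))
  expect_equal(normalize_boundary(pat), c(0, 0.5, 1))
  degenerate <- synthetic_pattern(function(m) pmax(m - 0.5, 0),
                                  tau = 0, marks = 0.2)
  expect_error(normalize_boundary(degenerate), "degenerate boundary.*spike 1")
})

test_that("subspace restriction keeps the right spikes and intensity", {
  pat <- synthetic_pattern(function(m) rep(2, length(m)),
                           tau = c(0.5, 1.0, 1.5),
                           marks = c(0.1, 0.5, 0.9))
  # full-domain restriction is a no-op
  full <- restrict_subspace(pat, c(0, 1))
  expect_equal(full$pattern$n, 3)
  expect_equal(full$ground$lambda, superposed_intensity(pat)$lambda)
  # measure-0.4 subset of a rectangular region: lambda_s = 0.4 on [0, 2]
  sub <- restrict_subspace(pat, c(0.3, 0.7))
  expect_equal(sub$pattern$n, 1)
  expect_true(all(abs(sub$ground$lambda[sub$ground$tau <= 2] - 0.4) < 1e-2))
  # a subset holding no spikes still carries the boundary intensity
  empty <- restrict_subspace(pat, c(0.91, 1.0))
  expect_equal(empty$pattern$n, 0)
  expect_gt(sum(empty$ground$lambda), 0)
  expect_error(restrict_subspace(pat, c(2, 3)), "intersect")
})

test_that("trains, patterns and covariates round-trip through files", {
  dir <- withr::local_tempdir()
  tr <- marked_train(c(3, 8, 15), cbind(c(11, 12, 11.5), c(1, 2, 3)),
                     T = 20, neuron = c(1L, 2L, 1L))
  f <- file.path(dir, "train.csv")
  write_marked_train(tr, f)
  back <- read_marked_train(f, T = 20)
  expect_equal(back$times, tr$times)
  expect_equal(back$marks, tr$marks)
  expect_equal(back$neuron, tr$neuron)
  cov <- simulate_ar1(0.9, 0.2, 50, seed = 4)
  fc <- file.path(dir, "cov.csv")
  write_covariate_csv(cov, fc)
  expect_equal(read_covariate_csv(fc)$values, cov$values)
  mod <- jmi_constant(1.5, c(0, 1), n_steps = 20)
  pat <- rescale_marked(marked_train(c(3, 8), c(0.2, 0.7), T = 20), mod)
  fp <- file.path(dir, "pattern.csv")
  write_rescaled_pattern(pat, fp)
  pback <- read_rescaled_pattern(fp)
  expect_equal(pback$tau, pat$tau)
  expect_equal(pback$region_volume, pat$region_volume, tolerance = 1e-12)
  expect_equal(second_rescale(pback), second_rescale(pat),
               tolerance = 1e-9)
  expect_error(marked_train(c(1, 1), c(0.1, 0.2), T = 5), "strictly")
})
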