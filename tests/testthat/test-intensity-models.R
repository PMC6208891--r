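test_that("constant model evaluates to its rate and integrates to rate x measure", {
  mod <- jmi_constant(0.7, c(0, 1), n_steps = 50)
  expect_equal(evaluate_jmi(mod, 10, 0.3), 0.7)
  expect_equal(evaluate_jmi(mod, 49.5, 0.9), 0.7)
  expect_equal(ground_intensity(mod, 10), 0.7)          # measure-1 domain
  mod2 <- jmi_constant(0.7, c(0, 3), n_steps = 50)
  expect_equal(ground_intensity(mod2, 10), 2.1)
  zero <- jmi_constant(0, c(0, 1), n_steps = 50)
  expect_equal(ground_intensity(zero, 10), 0)
})

test_that("place-field model matches the closed-form evaluation oracle", {
  cov <- fixed_covariate(x = -2)
  mod <- place_field_model(study1_params(), cov, history_enabled = FALSE)
  # peak place rate at the field center is exp(a1) = 0.15 spikes per step
  p <- study1_params()
  expect_equal(exp(p$a1), 0.15)
  # hand-computed: x = -2, m = 11, empty history:
  # 0.15 * phi(0; sd 0.3) + 0.15 * exp(-16) * phi(-1; sd 0.3)
  oracle <- 0.15 * dnorm(0, sd = 0.3) + 0.15 * exp(-16) * dnorm(1, sd = 0.3)
  expect_equal(evaluate_jmi(mod, 5, 11), oracle, tolerance = 1e-12)
  # mark densities are normalized, so the ground intensity collapses to the
  # sum of the place rates: 0.15 * (1 + exp(-16))
  expect_equal(ground_intensity(mod, 5), 0.15 * (1 + exp(-16)),
               tolerance = 1e-12)
})

test_that("quadrature ground intensity matches analytic Gaussian masses", {
  cov <- fixed_covariate(x = 0.5)
  mod <- place_field_model(study1_params(), cov, history_enabled = FALSE)
  # grid spanning +/- 6 sd at sd/20 spacing
  grid <- mark_grid(mod$mark_domain,
                    n = ceiling(diff(mod$mark_domain[1, ]) / (0.3 / 20)))
  q <- ground_intensity(mod, 3, method = "quadrature", grid = grid)
  a <- ground_intensity(mod, 3, method = "analytic")
  expect_lt(abs(q - a) / a, 1e-3)
})

test_that("evaluation is nonnegative across model families and random inputs", {
  set.seed(42)
  cov <- simulate_ar1(0.98, 0.3, 200, seed = 5)
  hist_tr <- marked_train(c(20, 50, 90), c(11, 12, 11.2), T = 200,
                          neuron = c(1L, 2L, 1L))
  pf <- place_field_model(study1_params(), cov, history_enabled = TRUE)
  mog <- small_mog(d = 2, n_steps = 200)
  for (i in 1:50) {
    t <- runif(1, 1, 200)
    m_pf <- matrix(runif(200, 9.3, 13.7), ncol = 1)
    expect_true(all(evaluate_jmi(pf, t, m_pf, history = hist_tr) >= 0))
    m_mog <- cbind(runif(100, 2, 8), runif(100, 2, 8))
    expect_true(all(evaluate_jmi(mog, t, m_mog) >= 0))
  }
})

test_that("history effects: refractoriness suppresses, excitation amplifies", {
  cov <- fixed_covariate(x = -2, n_steps = 200)
  mod <- place_field_model(study1_params(), cov, history_enabled = TRUE)
  base <- evaluate_jmi(mod, 52, 11)
  # a neuron-1 spike 2 steps earlier suppresses neuron 1's rate
  refr <- evaluate_jmi(mod, 52, 11,
                       history = marked_train(50, 11, T = 200, neuron = 1L))
  expect_lt(refr, base)
  # a neuron-2 spike r = 10 steps earlier amplifies neuron 1's rate
  exc <- evaluate_jmi(mod, 60, 11,
                      history = marked_train(50, 12, T = 200, neuron = 2L))
  expect_gt(exc, evaluate_jmi(mod, 60, 11))
})

test_that("history-free evaluation ignores the supplied history", {
  cov <- fixed_covariate(x = 1, n_steps = 100)
  mod <- place_field_model(study1_params(), cov, history_enabled = FALSE)
  h <- marked_train(c(10, 30), c(11, 12), T = 100, neuron = c(1L, 2L))
  expect_equal(evaluate_jmi(mod, 31, 11.5, history = h),
               evaluate_jmi(mod, 31, 11.5))
})

test_that("scale_model is identity at 1, linear, and component-wise", {
  mod <- jmi_constant(0.4, c(0, 1), n_steps = 20)
  expect_equal(evaluate_jmi(scale_model(mod, 1), 5, 0.5),
               evaluate_jmi(mod, 5, 0.5))
  expect_equal(evaluate_jmi(scale_model(mod, 1.6), 5, 0.5), 1.6 * 0.4)
  # two equal components scaled by (0.56, 1.6): ground intensity becomes
  # (0.56 + 1.6) * rho with rho the per-component rate
  cov <- fixed_covariate(x = 0, n_steps = 50)
  p <- study1_params(); p$mu_x1 <- 0; p$mu_x2 <- 0
  two <- place_field_model(p, cov, history_enabled = FALSE)
  rho <- ground_intensity(two, 5) / 2
  sc <- scale_model(two, component_factors = c(0.56, 1.6))
  expect_equal(ground_intensity(sc, 5), (0.56 + 1.6) * rho,
               tolerance = 1e-12)
  expect_error(scale_model(mod, component_factors = c(1, 2)),
               "length")
  expect_error(scale_model(mod, global_factor = -1), "positive")
})

test_that("validation: bad parameters and out-of-domain marks error", {
  cov <- fixed_covariate()
  p <- study1_params(); p$sigma_m1 <- NaN
  expect_error(place_field_model(p, cov), "non-finite")
  p <- study1_params(); p$sigma_x2 <- -1
  expect_error(place_field_model(p, cov), "sigma")
  mod <- place_field_model(study1_params(), cov, history_enabled = FALSE)
  expect_error(evaluate_jmi(mod, 5, 50), "outside")
  expect_error(ground_intensity(mod, 5, method = "quadrature"), "grid")
})

test_that("mixture model applies Sigma_c as the quadratic-form matrix", {
  mog <- small_mog(d = 2, n_steps = 100)
  m <- c(4.5, 4.5)
  x <- mog$covariate$values[10]
  oracle <- sum(vapply(1:2, function(c) {
    dev <- m - mog$mu[c, ]
    mog$lambda[c] * exp(-(x - mog$f[c])^2 / (2 * mog$sigma2[c])) *
      exp(-0.5 * drop(t(dev) %*% mog$Sigma[[c]] %*% dev))
  }, numeric(1)))
  expect_equal(evaluate_jmi(mog, 10, m), oracle, tolerance = 1e-12)
  expect_error(
    mog_model(1, 0, 1, matrix(0, 1, 2),
              list(matrix(c(1, 2, 0, 1), 2)), fixed_covariate()),
    "symmetric"
  )
  expect_error(
    mog_model(1, 0, 1, matrix(0, 1, 2),
              list(diag(c(1, -1))), fixed_covariate()),
    "positive definite"
  )
})

test_that("kernel model matches a hand-computed evaluation", {
  cov <- covariate_trajectory(c(0, 1, 2, 1, 0))
  mod <- kernel_model(spike_x = c(0.5, 1.5),
                      marks = rbind(c(4, 4), c(6, 6)), cov,
                      Bx = 1, Bm = 0.5, bx = 1)
  m <- c(4.2, 4.1); t <- 2
  D <- 1 * sum(dnorm(cov$values[t] - cov$values, sd = 1))
  oracle <- sum(vapply(1:2, function(n) {
    dnorm(cov$values[t] - mod$spike_x[n], sd = 1) / D *
      (2 * pi * 0.25)^(-1) *
      exp(-sum((m - mod$marks[n, ])^2) / (2 * 0.25))
  }, numeric(1)))
  expect_equal(evaluate_jmi(mod, t, m), oracle, tolerance = 1e-12)
  expect_error(kernel_model(0.5, matrix(4), cov, Bx = 0, Bm = 1, bx = 1),
               "bandwidth")
})

test_that("model JSON serialization round-trips evaluations", {
  tmp <- withr::local_tempfile(fileext = ".json")
  cov <- simulate_ar1(0.98, 0.3, 100, seed = 2)
  mod <- place_field_model(study1_params(), cov, history_enabled = TRUE)
  mod <- scale_model(mod, global_factor = 1.3)
  write_model_json(mod, tmp)
  back <- read_model_json(tmp)
  h <- marked_train(c(10, 40), c(11, 12), T = 100, neuron = c(1L, 2L))
  expect_equal(evaluate_jmi(back, 45, 11.4, history = h),
               evaluate_jmi(mod, 45, 11.4, history = h))
  mog <- small_mog(d = 2, n_steps = 100)
  write_model_json(mog, tmp)
  back2 <- read_model_json(tmp)
  expect_equal(evaluate_jmi(back2, 7, c(4.4, 5.1)),
               evaluate_jmi(mog, 7, c(4.4, 5.1)))
})
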