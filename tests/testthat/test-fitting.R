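test_that("MLE recovers place and mark parameters from simulated data", {
  cov <- simulate_ar1(0.98, 0.3, 16000, seed = 61)
  gen <- place_field_model(study1_params(), cov, history_enabled = FALSE)
  tr <- simulate_marked(gen, seed = 62)
  expect_gt(n_spikes(tr), 800)
  fit <- suppressWarnings(
    fit_place_mark_mle(tr, cov, list(family = "no_history"))
  )
  expect_lt(abs(fit$params$mu_m1 - 11), 0.15)
  expect_lt(abs(fit$params$mu_m2 - 12), 0.15)
  expect_lt(abs(fit$params$mu_x1 - (-2)), 0.2)
  expect_lt(abs(fit$params$mu_x2 - 2), 0.2)
  expect_true(all(unlist(fit$params[c("sigma_x1", "sigma_x2",
                                      "sigma_m1", "sigma_m2")]) > 0))
  # likelihood ascent from the moment-based start
  expect_gte(fit$logLik, fit$start_logLik - 1e-6)
  expect_error(
    fit_place_mark_mle(marked_train(numeric(0), matrix(0, 0, 1), T = 10),
                       cov),
    "insufficient"
  )
})

test_that("lag estimation: exact offsets, recovery, and null flatness", {
  # two deterministic trains offset by exactly 10 steps
  t2 <- seq(50, 950, by = 50)
  t1 <- t2 + 10
  all_t <- sort(c(t1, t2))
  mk <- ifelse(all_t %in% t1, 11, 12)  # group 1 low marks, group 2 high
  tr <- marked_train(all_t, mk, T = 1000)
  expect_equal(estimate_lag_moment(tr, 11.5, max_lag = 30)$r_hat, 10)
  # recovery from the full generative model: within +/- 1 of r = 10
  hits <- vapply(1:6, function(s) {
    cov <- simulate_ar1(0.98, 0.3, 10000, seed = 70 + s)
    mod <- place_field_model(study1_params(), cov, history_enabled = TRUE)
    trs <- simulate_marked_history(mod, seed = 170 + s)
    estimate_lag_moment(trs, 11.5, max_lag = 30)$r_hat
  }, numeric(1))
  expect_gte(sum(abs(hits - 10) <= 1), 5)
  # independent Poisson trains: no significant correlogram peak
  set.seed(81)
  ta <- sort(sample(1:5000, 150)) + 0.1
  tb <- sort(sample(1:5000, 150)) + 0.2
  allt <- sort(c(ta, tb))
  mki <- ifelse(allt %in% ta, 11, 12)
  null_res <- estimate_lag_moment(marked_train(allt, mki, T = 5000), 11.5)
  expect_false(null_res$significant)
  one_group <- marked_train(c(1, 2, 3), c(11, 11, 11), T = 10)
  expect_error(estimate_lag_moment(one_group, 11.5), "insufficient")
})

test_that("mixture fitting: single-component reduction and rate calibration", {
  fx <- make_tetrode_fixture(seed = 91, n_components = 1, hash_fraction = 0,
                             n_steps = 2000, expected_spikes = 250)
  tr <- fx$train
  cov <- fx$model$covariate
  fit1 <- fit_mog(tr, cov, n_components = 1, seed = 1)
  x_sp <- cov$values[ceiling(tr$times / cov$dt)]
  expect_equal(fit1$f, mean(x_sp), tolerance = 1e-6)
  expect_equal(as.numeric(fit1$mu), colMeans(tr$marks), tolerance = 1e-6)
  # expected count matches observed count after rate calibration
  comp <- mptrescale:::jmi_components(fit1, NULL)
  expect_lt(abs(sum(colSums(comp$time) * comp$dt * comp$mass) -
                  n_spikes(tr)) / n_spikes(tr), 0.02)
  expect_error(fit_mog(tr, cov, n_components = 60), "insufficient")
})

test_that("mixture fitting recovers well-separated components, reproducibly", {
  errs <- vapply(1:5, function(s) {
    fx <- make_tetrode_fixture(seed = 200 + s, n_components = 2,
                               hash_fraction = 0, n_steps = 2500,
                               expected_spikes = 400)
    fit <- fit_mog(fx$train, fx$model$covariate, n_components = 2, seed = 1)
    true_mu <- fx$model$mu
    # match components by nearest center
    perm <- if (sum((fit$mu[1, ] - true_mu[1, ])^2) <
                sum((fit$mu[1, ] - true_mu[2, ])^2)) 1:2 else 2:1
    max(abs(fit$mu[perm, ] - true_mu))
  }, numeric(1))
  expect_lt(median(errs), 0.1)
  fx <- make_tetrode_fixture(seed = 300, n_components = 2,
                             hash_fraction = 0, n_steps = 2000,
                             expected_spikes = 250)
  fa <- fit_mog(fx$train, fx$model$covariate, 2, seed = 9)
  fb <- fit_mog(fx$train, fx$model$covariate, 2, seed = 9)
  expect_identical(fa$mu, fb$mu)
  expect_identical(fa$lambda, fb$lambda)
})

test_that("leave-one-out bandwidth selection scores and selects correctly", {
  cov <- covariate_trajectory(c(0, 0.5, 1, 0.5, 0))
  tr <- marked_train(c(2, 4), rbind(4, 6), T = 5)
  one <- kb_bandwidth_cv(tr, cov, list(list(Bx = 1, Bm = 1, bx = 1)))
  expect_equal(one$best, list(Bx = 1, Bm = 1, bx = 1))
  expect_length(one$scores, 1)
  # two-spike toy: the leave-one-out intensity at spike 1 uses only
  # spike 2's kernels; hand-compute the estimator with N = 1
  x_sp <- cov$values[c(2, 4)]
  D <- function(t) sum(dnorm(cov$values[t] - cov$values, sd = 1))
  lam_loo1 <- dnorm(x_sp[1] - x_sp[2], sd = 1) / D(2) *
    dnorm(4 - 6, sd = 1)
  lam_loo2 <- dnorm(x_sp[2] - x_sp[1], sd = 1) / D(4) *
    dnorm(6 - 4, sd = 1)
  mod <- kernel_model(x_sp, rbind(4, 6), cov, Bx = 1, Bm = 1, bx = 1)
  comp <- mptrescale:::jmi_components(mod, NULL)
  integral <- sum(colSums(comp$time) * comp$dt)
  expect_equal(one$scores, log(lam_loo1) + log(lam_loo2) - integral,
               tolerance = 1e-9)
  expect_error(kb_bandwidth_cv(marked_train(1, matrix(4), T = 5), cov,
                               list(list(Bx = 1, Bm = 1, bx = 1))),
               "insufficient")
})

test_that("bandwidth selection prefers interior candidates on smooth data", {
  interior <- vapply(1:8, function(s) {
    fx <- make_tetrode_fixture(seed = 400 + s, n_components = 2,
                               hash_fraction = 0, n_steps = 1200,
                               expected_spikes = 120)
    cands <- lapply(c(0.02, 0.1, 0.5, 2.5), function(bm) {
      list(Bx = 0.3, Bm = bm, bx = 0.3)
    })
    sel <- kb_bandwidth_cv(fx$train, fx$model$covariate, cands)
    sel$best$Bm %in% c(0.1, 0.5)
  }, logical(1))
  expect_gte(mean(interior), 0.7)
})
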