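# Parameter estimation for the simulation-study model families and the
# clusterless estimators.

# Discretized point-process log-likelihood of a marked train under a model:
# sum_j log lambda(s_j, m_j | H_{s_j}) - int int lambda dt dm, with the same
# left-Riemann time quadrature as the rescaling module and analytic mark
# masses for the integral term.
pp_loglik <- function(model, train) {
  use_labels <- inherits(model, "sorted_pair_model")
  marks <- if (use_labels) {
    matrix(as.numeric(sort_labels(model, train$marks)), ncol = 1L)
  } else train$marks
  comp <- jmi_components(model, history = train)
  steps <- pmin(comp$n_steps, pmax(1L, ceiling(train$times / comp$dt)))
  lam <- rowSums(comp$time[steps, , drop = FALSE] * comp$markfun(marks))
  sum(log(pmax(lam, 1e-300))) - sum(colSums(comp$time) * comp$dt * comp$mass)
}

# Moment-based starting values: split spikes at the midpoint between the two
# mark clusters (k-means with deterministic quantile init), then group-wise
# sample moments in mark and position.
moment_start <- function(train, covariate) {
  m <- train$marks[, 1]
  x <- covariate$values[pmin(covariate$n_steps,
                             pmax(1L, ceiling(train$times / covariate$dt)))]
  centers <- matrix(stats::quantile(m, c(0.25, 0.75)), ncol = 1)
  km <- suppressWarnings(stats::kmeans(matrix(m, ncol = 1), centers))
  g <- km$cluster
  if (mean(m[g == 1]) > mean(m[g == 2])) g <- 3L - g  # group 1 = lower marks
  grab <- function(v, gi) { vi <- v[g == gi]; if (length(vi) < 2) v else vi }
  list(
    mu_x1 = mean(grab(x, 1L)), mu_x2 = mean(grab(x, 2L)),
    sigma_x1 = max(stats::sd(grab(x, 1L)), 0.05),
    sigma_x2 = max(stats::sd(grab(x, 2L)), 0.05),
    mu_m1 = mean(grab(m, 1L)), mu_m2 = mean(grab(m, 2L)),
    sigma_m1 = max(stats::sd(grab(m, 1L)), 0.01),
    sigma_m2 = max(stats::sd(grab(m, 2L)), 0.01)
  )
}

#' Maximum-likelihood fit of the place/mark Gaussian parameters
#'
#' Estimates the eight free parameters of the two-neuron place-field family
#' — place-field centers and widths (`mu_x1`, `mu_x2`, `sigma_x1`,
#' `sigma_x2`) and mark means and standard deviations (`mu_m1`, `mu_m2`,
#' `sigma_m1`, `sigma_m2`) — by maximizing the discretized point-process
#' log-likelihood, with the peak rates, history-kernel widths and excitatory
#' lag (`a1`, `a2`, `a3`, `sigma_1`, `sigma_2`, `r`) held fixed at the
#' values supplied in `structure`. Optimization is Nelder-Mead from
#' moment-based starting values (log-transformed widths).
#'
#' @param train a nonempty [marked_train()] (with neuron labels when fitting
#'   the history-dependent family).
#' @param covariate the [covariate_trajectory()] covering `[0, T]`.
#' @param structure list with `fixed` (named values for a1, a2, a3, sigma_1,
#'   sigma_2, r), `family` (`"full"`, `"no_history"`, or `"sorted"`), and
#'   `sort_threshold` for the sorted family.
#' @param maxit Nelder-Mead iteration cap.
#' @return object of class `fit_result`: `params` (complete parameter set),
#'   `model` (the fitted model), `logLik`, `start_logLik`, `converged`,
#'   `iterations`. Non-convergence attaches a warning.
#' @export
fit_place_mark_mle <- function(train, covariate,
                               structure = list(family = "full"),
                               maxit = 2000L) {
  stopifnot(inherits(train, "marked_train"),
            inherits(covariate, "covariate_trajectory"))
  if (n_spikes(train) == 0) {
    stop("insufficient data: cannot fit a model to a zero-spike train")
  }
  family <- structure$family %||% "full"
  fixed <- structure$fixed %||% study1_params()[c("a1", "a2", "a3",
                                                  "sigma_1", "sigma_2", "r")]
  thr <- structure$sort_threshold %||% 11.5
  free <- c("mu_x1", "mu_x2", "mu_m1", "mu_m2")
  pos <- c("sigma_x1", "sigma_x2", "sigma_m1", "sigma_m2")
  start <- moment_start(train, covariate)
  theta0 <- c(unlist(start[free]), log(unlist(start[pos])))
  build <- function(theta) {
    p <- c(fixed, as.list(stats::setNames(theta[seq_along(free)], free)),
           as.list(stats::setNames(exp(theta[length(free) + seq_along(pos)]),
                                   pos)))
    switch(family,
      full = place_field_model(p, covariate, history_enabled = TRUE),
      no_history = place_field_model(p, covariate, history_enabled = FALSE),
      sorted = sorted_pair_model(p, covariate, sort_threshold = thr),
      stop("unknown family: ", family)
    )
  }
  negll <- function(theta) {
    val <- tryCatch(-pp_loglik(build(theta), train), error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }
  start_ll <- -negll(theta0)
  opt <- stats::optim(theta0, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  converged <- opt$convergence == 0
  if (!converged) {
    warning("optimizer did not converge within ", maxit, " iterations")
  }
  model <- build(opt$par)
  params <- model$params
  structure(
    list(params = params, model = model, logLik = -opt$value,
         start_logLik = start_ll, converged = converged,
         iterations = opt$counts[["function"]], family = family),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Fit (%s family): logLik %.4g (start %.4g), %s after %d evaluations\n",
    x$family, x$logLik, x$start_logLik,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Method-of-moments estimate of the excitatory lag
#'
#' Splits spikes into two groups at a mark threshold, forms the
#' cross-correlogram from group-2 spikes to subsequent group-1 spikes on the
#' time grid, and returns the lag of the maximum coefficient. When no bin
#' exceeds the approximate white-noise band for independent Poisson trains,
#' the estimate is flagged as non-significant rather than rejected.
#'
#' @param train a [marked_train()].
#' @param sort_threshold mark cutoff defining the two groups.
#' @param max_lag largest lag examined (time steps).
#' @param smooth_sd standard deviation (in steps) of the Gaussian smoothing
#'   applied to the correlogram before taking the argmax; matching it to
#'   the excitatory-kernel width pools the spread-out peak across adjacent
#'   bins. `0` disables smoothing.
#' @return list: `r_hat` (lag of the smoothed-correlogram maximum), `lags`,
#'   `counts` (raw bin counts), `expected` (independence expectation per
#'   bin), `bound` (Bonferroni-corrected Poisson null quantile),
#'   `significant`.
#' @export
estimate_lag_moment <- function(train, sort_threshold = 11.5, max_lag = 30L,
                                smooth_sd = 2) {
  stopifnot(inherits(train, "marked_train"))
  m <- train$marks[, 1]
  s1 <- train$times[m <= sort_threshold] / train$dt
  s2 <- train$times[m > sort_threshold] / train$dt
  if (length(s1) == 0 || length(s2) == 0) {
    stop("insufficient data: both mark-threshold groups must be nonempty")
  }
  lags <- seq_len(max_lag)
  # pairwise forward lags group 2 -> group 1, binned to the nearest step
  counts <- integer(max_lag)
  for (s in s2) {
    dl <- round(s1 - s)
    dl <- dl[dl >= 1 & dl <= max_lag]
    if (length(dl)) counts <- counts + tabulate(dl, max_lag)
  }
  n_steps <- train$T / train$dt
  expected <- length(s1) * length(s2) / n_steps
  # exact Poisson null quantile, Bonferroni-corrected over the lag bins
  bound <- stats::qpois(1 - 0.05 / max_lag, expected)
  score <- counts
  if (smooth_sd > 0) {
    # matched-width Gaussian filter; edge-normalized so boundary lags are
    # not penalized for their truncated window
    for (l in lags) {
      w <- stats::dnorm(lags - l, sd = smooth_sd)
      score[l] <- sum(w * counts) / sum(w)
    }
  }
  r_hat <- lags[which.max(score)]
  list(r_hat = r_hat, lags = lags, counts = counts, expected = expected,
       bound = bound, significant = max(counts) > bound)
}

# Multivariate normal log-density with block structure (position scalar,
# mark vector with full covariance).
block_gauss_logdens <- function(x, M, f, s2, mu, cov_m) {
  dev <- sweep(M, 2L, mu, `-`)
  ch <- chol(cov_m)
  q <- colSums(backsolve(ch, t(dev), transpose = TRUE)^2)
  -0.5 * ((x - f)^2 / s2 + q) - 0.5 * log(s2) - sum(log(diag(ch))) -
    (1 + ncol(M)) / 2 * log(2 * pi)
}

#' Fit a mixture-of-Gaussians joint mark intensity
#'
#' Deterministic weighted-EM backend: seeded k-means clustering of the
#' spikes in joint (position-at-spike, mark) space initializes component
#' responsibilities; a fixed number of EM iterations with the model's block
#' structure (independent position and mark factors within a component)
#' refines centers, position variances and mark covariances; and component
#' rates are then calibrated so each component's expected spike count
#' matches its responsibility-weighted observed count (hence the model's
#' total expected count matches the observed count). Mark matrices are
#' stored as the precision-like matrices entering the intensity's quadratic
#' form; near-singular mark covariances are ridge-regularized with a
#' warning.
#'
#' @param train a [marked_train()] with at least `n_components * (d + 2)`
#'   spikes.
#' @param covariate the [covariate_trajectory()].
#' @param n_components number of Gaussian components (user-supplied).
#' @param seed RNG seed (the fit is reproducible byte-for-byte given it).
#' @param em_iter fixed number of EM refinement iterations.
#' @return the fitted [mog_model()].
#' @export
fit_mog <- function(train, covariate, n_components, seed = 1L,
                    em_iter = 25L) {
  stopifnot(inherits(train, "marked_train"),
            inherits(covariate, "covariate_trajectory"))
  N <- n_spikes(train); d <- ncol(train$marks)
  if (N < n_components * (d + 2)) {
    stop("insufficient data: need at least n_components * (d + 2) spikes")
  }
  x <- covariate$values[pmin(covariate$n_steps,
                             pmax(1L, ceiling(train$times / covariate$dt)))]
  Y <- cbind(x, train$marks)
  Z <- scale(Y)
  km <- with_seed(seed, stats::kmeans(Z, centers = n_components,
                                      nstart = 5L, iter.max = 50L))
  resp <- matrix(0, N, n_components)
  resp[cbind(seq_len(N), km$cluster)] <- 1
  ridge_warned <- FALSE
  for (it in seq_len(em_iter + 1L)) {
    nk <- colSums(resp)
    f <- as.numeric(crossprod(resp, x) / nk)
    s2 <- vapply(seq_len(n_components), function(c) {
      max(sum(resp[, c] * (x - f[c])^2) / nk[c], 1e-4)
    }, numeric(1))
    mu <- crossprod(resp, train$marks) / nk
    covs <- lapply(seq_len(n_components), function(c) {
      dev <- sweep(train$marks, 2L, mu[c, ], `-`)
      S <- crossprod(dev * resp[, c], dev) / nk[c]
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
        if (!ridge_warned) {
          warning("near-singular component mark covariance; ",
                  "ridge regularization applied")
          ridge_warned <<- TRUE
        }
        S <- S + diag(1e-6, d)
      }
      S
    })
    if (it > em_iter) break
    logd <- vapply(seq_len(n_components), function(c) {
      block_gauss_logdens(x, train$marks, f[c], s2[c], mu[c, ], covs[[c]])
    }, numeric(N))
    logd <- matrix(logd, nrow = N) +
      rep(log(pmax(nk / N, 1e-12)), each = N)
    mx <- apply(logd, 1L, max)
    resp <- exp(logd - mx)
    resp <- resp / rowSums(resp)
  }
  Sigma <- lapply(covs, solve)
  model <- mog_model(rep(1, n_components), f, s2, mu, Sigma, covariate)
  # rate calibration: expected count per component = weighted observed count
  comp <- jmi_components(model, NULL)
  e_c <- colSums(comp$time) * comp$dt * comp$mass
  model$lambda <- as.numeric(nk / e_c)
  model
}

#' Leave-one-out bandwidth selection for the kernel intensity estimator
#'
#' For each candidate bandwidth set, evaluates every spike under the kernel
#' estimator built from all other spikes (its own kernel excluded), forms
#' the point-process log-likelihood
#' \eqn{\sum_j \log \hat\lambda_{-j}(s_j, m_j) - \int\int \hat\lambda\,
#' dt\, dm}, and returns the candidate maximizing it together with all
#' scores.
#'
#' @param train a [marked_train()] with at least 2 spikes.
#' @param covariate the [covariate_trajectory()].
#' @param candidates data frame (or list of lists) with columns/fields
#'   `Bx`, `Bm`, `bx`.
#' @return list: `best` (the selected bandwidths), `scores` (LOO
#'   log-likelihood per candidate), `model` (the kernel model built from
#'   all spikes at the selected bandwidths).
#' @export
kb_bandwidth_cv <- function(train, covariate, candidates) {
  stopifnot(inherits(train, "marked_train"))
  if (n_spikes(train) < 2) {
    stop("insufficient data: leave-one-out selection needs at least 2 spikes")
  }
  if (is.data.frame(candidates)) {
    candidates <- lapply(seq_len(nrow(candidates)),
                         function(i) as.list(candidates[i, ]))
  }
  if (length(candidates) == 0) stop("candidates must be nonempty")
  x_sp <- covariate$values[pmin(covariate$n_steps,
                                pmax(1L, ceiling(train$times /
                                                   covariate$dt)))]
  scores <- vapply(candidates, function(cand) {
    mod <- kernel_model(x_sp, train$marks, covariate,
                        Bx = cand$Bx, Bm = cand$Bm, bx = cand$bx)
    comp <- jmi_components(mod, NULL)
    steps <- pmin(comp$n_steps, pmax(1L, ceiling(train$times / comp$dt)))
    At <- comp$time[steps, , drop = FALSE]        # spike x training-spike
    phi <- comp$markfun(train$marks)
    contrib <- At * phi
    lam_loo <- rowSums(contrib) - diag(contrib)   # self-kernel excluded
    sum(log(pmax(lam_loo, 1e-300))) - sum(colSums(comp$time) * comp$dt)
  }, numeric(1))
  best <- candidates[[which.max(scores)]]
  mod <- kernel_model(x_sp, train$marks, covariate,
                      Bx = best$Bx, Bm = best$Bm, bx = best$bx)
  list(best = best, scores = scores, model = mod)
}
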