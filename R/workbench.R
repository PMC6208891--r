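# End-to-end simulation studies and the command-line entry point.

gof_row <- function(label, pattern, initial_strips = 20L) {
  pe <- tryCatch(pearson_uniformity(pattern, initial_strips),
                 error = function(e) NULL)
  ks <- tryCatch(ks_pipeline(pattern, "second_rescale"),
                 error = function(e) NULL)
  data.frame(
    model = label, n = pattern$n,
    region_volume = pattern$region_volume,
    pearson_X2 = if (is.null(pe)) NA_real_ else pe$statistic,
    pearson_df = if (is.null(pe)) NA_integer_ else pe$df,
    pearson_p = if (is.null(pe)) NA_real_ else pe$p_value,
    ks_D = if (is.null(ks)) NA_real_ else ks$statistic,
    ks_p = if (is.null(ks)) NA_real_ else ks$p_value,
    stringsAsFactors = FALSE
  )
}

#' Simulation study: candidate-model comparison with history dependence
#'
#' Simulates an AR(1) position covariate and a spike train from the
#' two-neuron history-dependent place-field population (default parameters
#' from [study1_params()]), then runs the full rescaling goodness-of-fit
#' pipeline (Pearson uniformity + KS after second rescaling) under four
#' candidate models: the true model with true parameters; the same
#' structure with maximum-likelihood parameter estimates; the model with
#' history dependence omitted (estimated); and the crudely threshold-sorted
#' pair (estimated, excitatory lag by the cross-correlogram method of
#' moments).
#'
#' @param seed RNG seed for the whole study.
#' @param n_steps trajectory length (time steps).
#' @param params generating parameters.
#' @return object of class `study_report`: `results` (one row per
#'   candidate), `patterns`, `train`, `fits`, `seed`, `config`.
#' @export
run_study1 <- function(seed = 1L, n_steps = 10000L,
                       params = study1_params()) {
  seeds <- sub_seeds(seed, 2L)
  cov <- simulate_ar1(0.98, 0.3, n_steps, seed = seeds[1])
  true_model <- place_field_model(params, cov, history_enabled = TRUE)
  train <- simulate_marked_history(true_model, seed = seeds[2])
  fixed <- params[c("a1", "a2", "a3", "sigma_1", "sigma_2", "r")]

  fit_full <- fit_place_mark_mle(train, cov,
                                 list(family = "full", fixed = fixed))
  fit_nh <- fit_place_mark_mle(train, cov,
                               list(family = "no_history", fixed = fixed))
  r_hat <- estimate_lag_moment(train, sort_threshold = 11.5)$r_hat
  fixed_sorted <- fixed; fixed_sorted$r <- r_hat
  fit_sorted <- fit_place_mark_mle(
    train, cov,
    list(family = "sorted", fixed = fixed_sorted, sort_threshold = 11.5)
  )

  candidates <- list(
    true_true = true_model,
    true_mle = fit_full$model,
    missing_history = fit_nh$model,
    sorted = fit_sorted$model
  )
  patterns <- lapply(candidates, function(m) rescale_marked(train, m))
  results <- do.call(rbind, Map(gof_row, names(patterns), patterns))
  structure(
    list(results = results, patterns = patterns, train = train,
         fits = list(full = fit_full, no_history = fit_nh,
                     sorted = fit_sorted, r_hat = r_hat),
         seed = seed,
         config = list(study = "study1", n_steps = n_steps,
                       params = params)),
    class = "study_report"
  )
}

#' Simulation study: scaled candidate models without history
#'
#' Simulates from the history-free two-neuron model and evaluates four
#' candidates: the true model; the intensity uniformly scaled by 0.56 and
#' by 1.6 (wrong overall rate, correct mark structure — the KS test should
#' reject while the Pearson test does not); and the model with the two
#' component intensities scaled separately by 0.56 and 1.6 (roughly
#' preserving the overall rate but distorting the mark structure — the
#' Pearson test should reject while the KS test does not). Records the KS
#' deviation sign (empirical minus model CDF at the largest gap) for the
#' scaled candidates.
#'
#' @inheritParams run_study1
#' @export
run_study2 <- function(seed = 1L, n_steps = 10000L,
                       params = study1_params()) {
  seeds <- sub_seeds(seed, 2L)
  cov <- simulate_ar1(0.98, 0.3, n_steps, seed = seeds[1])
  true_model <- place_field_model(params, cov, history_enabled = FALSE)
  train <- simulate_marked(true_model, seed = seeds[2])
  candidates <- list(
    true = true_model,
    scaled_0.56 = scale_model(true_model, global_factor = 0.56),
    scaled_1.6 = scale_model(true_model, global_factor = 1.6),
    component_scaled = scale_model(true_model,
                                   component_factors = c(0.56, 1.6))
  )
  patterns <- lapply(candidates, function(m) rescale_marked(train, m))
  results <- do.call(rbind, Map(gof_row, names(patterns), patterns))
  results$ks_sign <- vapply(patterns, function(p) {
    ks <- tryCatch(ks_pipeline(p, "second_rescale"),
                   error = function(e) NULL)
    if (is.null(ks)) return(NA_real_)
    dev <- ks$cdf$empirical - ks$cdf$model
    sign(dev[which.max(abs(dev))])
  }, numeric(1))
  structure(
    list(results = results, patterns = patterns, train = train,
         seed = seed,
         config = list(study = "study2", n_steps = n_steps,
                       params = params)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report (%s), seed %d, %d spikes\n",
              x$config$study, x$seed, n_spikes(x$train)))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Power analysis of the rescaling goodness-of-fit tests
#'
#' For each duration, repeatedly simulates a spike train from the full
#' history-dependent model (redrawing the AR(1) covariate each replicate),
#' rescales it under three candidates — the true model, the
#' missing-history model, and the threshold-sorted pair, all at the
#' generating parameter values — and tabulates the fraction of replicates
#' in which each test rejects at the given significance level.
#'
#' @param durations vector of horizon lengths in time steps.
#' @param replicates simulated datasets per duration (>= 10).
#' @param seed master RNG seed.
#' @param alpha significance level.
#' @param params generating parameters.
#' @return object of class `power_curve`: a data frame `curve` with one row
#'   per (duration, candidate) and columns for expected spike count and
#'   rejection fractions of both tests, plus `replicates`, `alpha`, `seed`.
#' @export
run_power_analysis <- function(durations = c(500, 1000, 2000, 5000, 10000,
                                             20000),
                               replicates = 100L, seed = 1L, alpha = 0.05,
                               params = study1_params()) {
  if (replicates < 10) stop("use at least 10 replicates")
  cand_names <- c("true", "missing_history", "sorted")
  rows <- list()
  for (di in seq_along(durations)) {
    d <- as.integer(durations[di])
    seeds <- sub_seeds(seed + di, 2L * replicates)
    pearson_p <- matrix(NA_real_, replicates, 3L,
                        dimnames = list(NULL, cand_names))
    ks_p <- pearson_p
    counts <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      cov <- simulate_ar1(0.98, 0.3, d, seed = seeds[2 * rep - 1])
      true_model <- place_field_model(params, cov, history_enabled = TRUE)
      train <- simulate_marked_history(true_model, seed = seeds[2 * rep])
      counts[rep] <- n_spikes(train)
      cands <- list(
        true = true_model,
        missing_history = place_field_model(params, cov,
                                            history_enabled = FALSE),
        sorted = sorted_pair_model(params, cov, sort_threshold = 11.5)
      )
      for (cn in cand_names) {
        pat <- rescale_marked(train, cands[[cn]])
        row <- gof_row(cn, pat)
        pearson_p[rep, cn] <- row$pearson_p
        ks_p[rep, cn] <- row$ks_p
      }
    }
    for (cn in cand_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        duration = d, model = cn,
        mean_spikes = mean(counts),
        pearson_reject = mean(pearson_p[, cn] < alpha, na.rm = TRUE),
        ks_reject = mean(ks_p[, cn] < alpha, na.rm = TRUE),
        n_valid_pearson = sum(!is.na(pearson_p[, cn])),
        n_valid_ks = sum(!is.na(ks_p[, cn])),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(curve = do.call(rbind, rows), replicates = replicates,
         alpha = alpha, seed = seed, durations = durations),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve: %d replicates per duration, alpha = %g\n",
              x$replicates, x$alpha))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Write a study report or power curve to a results directory
#'
#' Creates `dir` with `config.json`, `tests.json` (or `power.csv`) and, for
#' studies, the train and per-candidate rescaled patterns.
#'
#' @param x a `study_report` or `power_curve`.
#' @param dir output directory.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "study_report")) {
    jsonlite::write_json(c(x$config, list(seed = x$seed)),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(x$results, file.path(dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    dir.create(file.path(dir, "trains"), showWarnings = FALSE)
    dir.create(file.path(dir, "patterns"), showWarnings = FALSE)
    write_marked_train(x$train, file.path(dir, "trains", "train.csv"))
    for (nm in names(x$patterns)) {
      write_rescaled_pattern(x$patterns[[nm]],
                             file.path(dir, "patterns",
                                       paste0(nm, ".csv")))
    }
  } else if (inherits(x, "power_curve")) {
    jsonlite::write_json(list(seed = x$seed, replicates = x$replicates,
                              alpha = x$alpha, durations = x$durations),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(x$curve, file.path(dir, "power.csv"),
                     row.names = FALSE)
  } else {
    stop("unsupported report object")
  }
  invisible(dir)
}
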