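#' Pearson chi-square test of uniformity over the rescaled region
#'
#' Partitions the mark axis into equal-width strips, takes as subregion
#' \eqn{R_i} the part of the rescaled region above strip `i` with volume
#' \eqn{|R_i| = \int_{strip} b(m) dm}, and compares observed spike counts
#' \eqn{r_i} with expected counts \eqn{n p_i}, \eqn{p_i = |R_i|/|R|}, via
#' \deqn{X^2 = \sum_i (r_i - n p_i)^2 / (n p_i),}
#' referred to a chi-square distribution with `M - 1` degrees of freedom.
#' Adjacent strips are merged left-to-right until every expected count is at
#' least `min_expected`. For patterns with multidimensional marks the strips
#' are taken along `strip_dim` (first mark dimension by default); for
#' discrete-mark (sorted) patterns the subregions are the cluster atoms.
#'
#' @param pattern a `rescaled_pattern` from [rescale_marked()].
#' @param initial_strips number of equal-width strips before merging (>= 2).
#' @param min_expected smallest admissible expected count per subregion.
#' @param strip_dim mark dimension along which to partition.
#' @return object of class `uniformity_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `n_subregions`, `n`.
#' @export
pearson_uniformity <- function(pattern, initial_strips = 20L,
                               min_expected = 5, strip_dim = 1L) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  n <- pattern$n
  if (n == 0) stop("insufficient data: the rescaled pattern has no spikes")
  if (pattern$region_volume <= 0) stop("zero-volume rescaled region")
  if (pattern$discrete) {
    atoms <- sort(unique(pattern$grid$points[, 1]))
    vol <- vapply(atoms, function(a) {
      sel <- pattern$grid$points[, 1] == a
      sum(pattern$grid$weights[sel] * pattern$b_grid[sel])
    }, numeric(1))
    cnt <- vapply(atoms, function(a) sum(pattern$marks[, 1] == a), numeric(1))
  } else {
    if (initial_strips < 2) stop("initial_strips must be at least 2")
    pts <- pattern$grid$points[, strip_dim]
    lo <- pattern$grid$domain[strip_dim, 1]
    hi <- pattern$grid$domain[strip_dim, 2]
    edges <- seq(lo, hi, length.out = initial_strips + 1L)
    idx_g <- pmin(initial_strips,
                  pmax(1L, findInterval(pts, edges, rightmost.closed = TRUE)))
    vol <- vapply(seq_len(initial_strips), function(i) {
      sel <- idx_g == i
      sum(pattern$grid$weights[sel] * pattern$b_grid[sel])
    }, numeric(1))
    idx_s <- pmin(initial_strips,
                  pmax(1L, findInterval(pattern$marks[, strip_dim], edges,
                                        rightmost.closed = TRUE)))
    cnt <- tabulate(idx_s, nbins = initial_strips)
  }
  p <- vol / sum(vol)
  # merge adjacent strips left-to-right until every expected count passes
  exp_cnt <- n * p
  grp <- integer(length(p)); g <- 1L; acc <- 0
  for (i in seq_along(p)) {
    grp[i] <- g
    acc <- acc + exp_cnt[i]
    if (acc >= min_expected && i < length(p)) { g <- g + 1L; acc <- 0 }
  }
  if (acc < min_expected && g > 1L) grp[grp == g] <- g - 1L
  obs <- as.numeric(tapply(cnt, grp, sum))
  expd <- as.numeric(tapply(exp_cnt, grp, sum))
  M <- length(obs)
  if (M < 2) {
    stop("insufficient data: fewer than 2 subregions satisfy the ",
         "expected-count rule")
  }
  stat <- sum((obs - expd)^2 / expd)
  structure(
    list(statistic = stat, df = M - 1L,
         p_value = stats::pchisq(stat, df = M - 1L, lower.tail = FALSE),
         observed = obs, expected = expd, n_subregions = M, n = n),
    class = "uniformity_test"
  )
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat(sprintf(
    "Pearson uniformity test: X^2 = %.4g on %d df, p = %.4g (M = %d, n = %d)\n",
    x$statistic, x$df, x$p_value, x$n_subregions, x$n
  ))
  invisible(x)
}

# Asymptotic Kolmogorov distribution survival function at lambda = sqrt(n) D.
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov test against an exponential interval law
#'
#' Tests whether positive intervals follow an Exp(`rate`) distribution:
#' \eqn{D = \sup_z |\hat F(z) - (1 - e^{-rate\, z})|} evaluated at the step
#' points of the empirical CDF, with the asymptotic Kolmogorov p-value and a
#' 95 percent band halfwidth of \eqn{1.36/\sqrt{n}} for the KS plot.
#'
#' @param intervals positive interval values.
#' @param rate exponential rate parameter (> 0).
#' @return object of class `ks_result`: `statistic`, `p_value`, `n`,
#'   `band_halfwidth`, and `cdf` (a data frame of model-vs-empirical CDF
#'   pairs at the sorted sample points, for KS plots).
#' @export
ks_exp_test <- function(intervals, rate = 1) {
  intervals <- as.numeric(intervals)
  n <- length(intervals)
  if (n < 1) stop("need at least one interval")
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must be positive and finite")
  }
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  z <- sort(intervals)
  Fm <- 1 - exp(-rate * z)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fm, Fm - (i - 1) / n))
  structure(
    list(statistic = D, p_value = kolmogorov_sf(sqrt(n) * D), n = n,
         band_halfwidth = 1.36 / sqrt(n),
         cdf = data.frame(x = z, model = Fm, empirical = i / n)),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS test: D = %.4g, n = %d, p = %.4g (95%% band +/- %.4g)\n",
              x$statistic, x$n, x$p_value, x$band_halfwidth))
  invisible(x)
}

#' KS goodness-of-fit pipelines on a rescaled pattern
#'
#' Three routes from a rescaled pattern to a KS test of an exponential
#' interval law:
#' \itemize{
#'   \item `"second_rescale"`: superpose the rescaled times over marks,
#'     rescale once more by the superposed ground intensity
#'     ([second_rescale()]), and test the intervals against Exp(1).
#'   \item `"normalized"`: divide each rescaled time by the boundary at its
#'     mark ([normalize_boundary()]); the sorted normalized times on `[0,1]`
#'     are tested against Exp(`n`), `n` the observed spike count.
#'   \item `"subspace"`: restrict to a mark interval `subset`
#'     ([restrict_subspace()]), second-rescale under the subspace ground
#'     intensity, and test against Exp(1).
#' }
#'
#' @param pattern a `rescaled_pattern` (at least 2 spikes).
#' @param variant one of `"second_rescale"`, `"normalized"`, `"subspace"`.
#' @param subset mark interval(s) for the subspace variant.
#' @return a `ks_result`.
#' @export
ks_pipeline <- function(pattern,
                        variant = c("second_rescale", "normalized",
                                    "subspace"),
                        subset = NULL) {
  stopifnot(inherits(pattern, "rescaled_pattern"))
  variant <- match.arg(variant)
  if (variant == "subspace") {
    if (is.null(subset)) stop("the subspace variant requires a mark subset")
    pattern <- restrict_subspace(pattern, subset)$pattern
    variant <- "second_rescale"
  }
  if (pattern$n < 2) {
    stop("insufficient data: need at least 2 spikes for interval tests")
  }
  if (variant == "second_rescale") {
    u <- second_rescale(pattern)
    ks_exp_test(positive_intervals(u), rate = 1)
  } else {
    tt <- sort(normalize_boundary(pattern))
    ks_exp_test(positive_intervals(tt), rate = pattern$n)
  }
}

# Successive differences with degenerate (tied) values floored at a tiny
# positive length. Ties arise only when rescaled times saturate the
# grid-represented boundary — i.e. under badly misfit models — and the
# floor lets the KS statistic register that misfit instead of erroring.
positive_intervals <- function(u, floor_at = 1e-12) {
  iv <- diff(c(0, u))
  iv[iv <= floor_at] <- floor_at
  iv
}

#' Autocorrelation of rescaled interspike intervals
#'
#' Under a correct model the rescaled intervals are i.i.d. Exp(1), so their
#' sample autocorrelation should show no structure: roughly 5 percent of
#' lags outside the two-sided white-noise bounds \eqn{\pm 1.96/\sqrt{n}}.
#'
#' @param intervals positive interval values.
#' @param max_lag largest lag (requires `n > max_lag + 1`).
#' @return list with `lag`, `acf`, `bound`, `n`, and `n_outside` (lags
#'   beyond the bounds).
#' @export
isi_autocorrelation <- function(intervals, max_lag = 20L) {
  intervals <- as.numeric(intervals)
  n <- length(intervals)
  if (max_lag < 1) stop("max_lag must be positive")
  if (n <= max_lag + 1) stop("need n > max_lag + 1 intervals")
  if (stats::var(intervals) == 0) {
    stop("degenerate input: intervals have zero variance")
  }
  a <- stats::acf(intervals, lag.max = max_lag, plot = FALSE)$acf[-1]
  bound <- 1.96 / sqrt(n)
  list(lag = seq_len(max_lag), acf = as.numeric(a), bound = bound, n = n,
       n_outside = sum(abs(a) > bound))
}

#' Serialize a test result to JSON
#'
#' @param x a `uniformity_test` or `ks_result`.
#' @param path output path.
#' @export
write_test_json <- function(x, path) {
  obj <- unclass(x)
  if (!is.null(obj$cdf)) obj$cdf <- NULL  # plot pairs export separately
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export KS plot point pairs as CSV
#' @param x a `ks_result`.
#' @param path output CSV path.
#' @export
write_ks_plot_csv <- function(x, path) {
  stopifnot(inherits(x, "ks_result"))
  utils::write.csv(x$cdf, path, row.names = FALSE)
  invisible(path)
}
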