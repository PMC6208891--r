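# JSON round-trip for model specifications: family name + named parameters +
# either an inline covariate or a reference to a covariate CSV.

#' Write / read a joint mark intensity model as JSON
#'
#' Serializes the model family name and named parameters. The covariate is
#' written inline unless `covariate_file` is given, in which case only the
#' file reference is stored (and resolved relative to the JSON file on read).
#'
#' @param model a joint mark intensity model (constant, place-field, sorted
#'   pair, mixture-of-Gaussians, or kernel family).
#' @param path JSON file path.
#' @param covariate_file optional path to a covariate CSV to reference
#'   instead of inlining the trajectory.
#' @return `read_model_json` returns the model; `write_model_json` returns
#'   `path` invisibly.
#' @export
write_model_json <- function(model, path, covariate_file = NULL) {
  stopifnot(inherits(model, "jmi"))
  fam <- class(model)[1]
  spec <- switch(fam,
    jmi_constant = list(rate = model$rate,
                        mark_domain = model$mark_domain,
                        n_steps = model$n_steps, dt = model$dt),
    pfp_model = list(params = model$params,
                     history_enabled = model$history_enabled),
    sorted_pair_model = list(params = model$params,
                             sort_threshold = model$sort_threshold),
    mog_model = list(lambda = model$lambda, f = model$f,
                     sigma2 = model$sigma2, mu = model$mu,
                     Sigma = model$Sigma, mark_domain = model$mark_domain),
    kernel_model = list(spike_x = model$spike_x, marks = model$marks,
                        occupancy_x = model$occupancy_x, Bx = model$Bx,
                        Bm = model$Bm, bx = model$bx,
                        denom_floor = model$denom_floor),
    stop("unsupported model family: ", fam)
  )
  obj <- list(family = fam, spec = spec,
              scale_global = model$scale_global %||% 1,
              scale_components = model$scale_components)
  if (fam %in% c("pfp_model", "sorted_pair_model", "mog_model",
                 "kernel_model")) {
    if (is.null(covariate_file)) {
      obj$covariate <- list(values = model$covariate$values,
                            dt = model$covariate$dt)
    } else {
      obj$covariate_file <- covariate_file
    }
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model JSON not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- NULL
  if (!is.null(obj$covariate)) {
    cov <- covariate_trajectory(obj$covariate$values, dt = obj$covariate$dt)
  } else if (!is.null(obj$covariate_file)) {
    ref <- obj$covariate_file
    if (!file.exists(ref)) ref <- file.path(dirname(path), ref)
    cov <- read_covariate_csv(ref)
  }
  s <- obj$spec
  model <- switch(obj$family,
    jmi_constant = jmi_constant(s$rate, matrix(s$mark_domain, ncol = 2),
                                n_steps = s$n_steps, dt = s$dt),
    pfp_model = place_field_model(as.list(s$params), cov,
                                  history_enabled = s$history_enabled),
    sorted_pair_model = sorted_pair_model(as.list(s$params), cov,
                                          sort_threshold = s$sort_threshold),
    mog_model = {
      Sig <- s$Sigma
      if (is.array(Sig) && length(dim(Sig)) == 3) {
        Sig <- lapply(seq_len(dim(Sig)[1]), function(i) Sig[i, , ])
      } else if (!is.list(Sig)) {
        Sig <- list(as.matrix(Sig))
      }
      mog_model(s$lambda, s$f, s$sigma2, matrix(s$mu, ncol = length(Sig[[1]][1, ])),
                Sig, cov, mark_domain = matrix(s$mark_domain, ncol = 2))
    },
    kernel_model = kernel_model(s$spike_x, as.matrix(s$marks), cov,
                                occupancy_x = s$occupancy_x, Bx = s$Bx,
                                Bm = s$Bm, bx = s$bx,
                                denom_floor = s$denom_floor),
    stop("unknown model family in JSON: ", obj$family)
  )
  if (length(obj$scale_components)) {
    model$scale_components <- as.numeric(unlist(obj$scale_components))
  }
  if (!is.null(obj$scale_global) && obj$scale_global != 1) {
    model$scale_global <- obj$scale_global
  }
  model
}
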