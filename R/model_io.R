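MODEL_SCHEMA_VERSION <- 1L

#' Write a fitted ridge model to a JSON bundle
#'
#' The bundle stores the contribution vector, both precisions, the posterior
#' covariance, the moiety index and the toolkit name/version (moiety keys
#' are canonicalization-dependent, so a model is only valid with the
#' toolkit that produced its keys). Numbers are written at full precision.
#'
#' @param model A \code{ridge_model}.
#' @param path Output path (\code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ridge_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    model_kind = "bayesian_ridge",
    moiety_index = model$moiety_index,
    dgG = unname(model$dgG),
    alpha = model$alpha, beta = model$beta, lambda = model$lambda,
    S_N = model$S_N,
    n_obs = model$n_obs, mse = model$mse,
    radii = model$radii, stereo = model$stereo,
    toolkit = model$toolkit, toolkit_version = model$toolkit_version
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a ridge model bundle written by \code{\link{write_model}}
#'
#' @param path Path to the JSON bundle.
#' @return A \code{ridge_model}.
#' @export
read_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(as.integer(p$schema_version), MODEL_SCHEMA_VERSION)) {
    mt_error(sprintf("unsupported model schema version %s", p$schema_version),
             "mt_input_error")
  }
  S_N <- matrix(unlist(p$S_N), nrow = length(p$moiety_index), byrow = FALSE)
  if (is.matrix(p$S_N)) S_N <- p$S_N
  dimnames(S_N) <- list(p$moiety_index, p$moiety_index)
  structure(list(
    dgG = stats::setNames(as.numeric(p$dgG), p$moiety_index),
    alpha = p$alpha, beta = p$beta, lambda = p$lambda,
    S_N = S_N, moiety_index = p$moiety_index,
    n_obs = p$n_obs, n_moieties = length(p$moiety_index), n_iter = NA_integer_,
    mse = p$mse, radii = p$radii, stereo = p$stereo,
    toolkit = p$toolkit, toolkit_version = p$toolkit_version
  ), class = "ridge_model")
}

#' Percent improvement of a metric relative to a reference
#'
#' \code{100 * (reference - new) / reference}: e.g. an error falling from
#' 45.20 to 9.60 is a 78.76\% improvement.
#'
#' @param reference Reference (old) value.
#' @param new Improved (new) value.
#' @return Percent improvement (vectorized).
#' @export
percent_improvement <- function(reference, new) {
  100 * (reference - new) / reference
}

#' Coverage of a subset as a percentage
#'
#' @param n_covered Number of covered items.
#' @param n_total Total number of items.
#' @return \code{100 * n_covered / n_total}.
#' @export
coverage_percent <- function(n_covered, n_total) {
  100 * n_covered / n_total
}

#' Percent increase of a count over a baseline
#'
#' \code{100 * (new - baseline) / baseline}; used for coverage-gain
#' reporting.
#'
#' @param baseline Baseline count.
#' @param new New count.
#' @return Percent increase.
#' @export
percent_increase <- function(baseline, new) {
  100 * (new - baseline) / baseline
}
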