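#' Assemble a training set from stoichiometry, incidence and observations
#'
#' The design matrix for the regression is \eqn{X = S^T G}: one row per
#' reaction, one column per moiety, entries the net moiety changes.
#'
#' @param S Stoichiometric matrix, compounds x reactions (signed integers),
#'   with row names matching the rows of \code{G}.
#' @param G Moiety incidence matrix from \code{\link{build_incidence}}.
#' @param y Observed standard reaction Gibbs energies (kJ/mol), one per
#'   reaction, already standardized to the reference pseudoisomers.
#' @return A \code{training_set} list with \code{S}, \code{G}, \code{y} and
#'   the derived \code{X}.
#' @export
training_set <- function(S, G, y) {
  stopifnot(is.matrix(S), is.matrix(G) || inherits(G, "moiety_incidence"))
  if (!all(rownames(S) == rownames(G))) {
    mt_error("row names of S must match row names of G", "mt_input_error")
  }
  if (length(y) != ncol(S)) {
    mt_error("length(y) must equal the number of reactions (columns of S)",
             "mt_input_error")
  }
  if (anyNA(y)) mt_error("observations y must not contain NA", "mt_input_error")
  X <- t(S) %*% unclass(G)
  structure(list(S = S, G = G, y = as.numeric(y), X = X,
                 radii = attr(G, "radii"), stereo = attr(G, "stereo")),
            class = "training_set")
}

as_design <- function(train) {
  if (inherits(train, "training_set")) list(X = train$X, y = train$y)
  else mt_error("expected a training_set", "mt_input_error")
}

#' Fit moiety contributions by Bayesian ridge regression
#'
#' Places an isotropic zero-mean Gaussian prior with precision \eqn{\alpha}
#' on the moiety contributions and a Gaussian likelihood with noise precision
#' \eqn{\beta} on the observations. The posterior mode equals the ridge
#' solution with penalty \eqn{\lambda = \alpha/\beta}; there is no intercept,
#' so a reaction with zero net moiety change predicts exactly 0. Unless both
#' precisions are supplied, they are optimized by MacKay-style evidence
#' maximization (iterative re-estimation of \eqn{\alpha} and \eqn{\beta}
#' from the effective number of well-determined parameters), which in
#' practice converges to the same optimum from any initialization.
#'
#' @param train A \code{\link{training_set}}, or a design matrix \code{X}
#'   (reactions x moieties) if \code{y} is given.
#' @param y Observations, only when \code{train} is a plain matrix.
#' @param alpha,beta Optional fixed precisions; supply both to skip evidence
#'   maximization (used for oracle comparisons and fixed-\eqn{\lambda} fits).
#' @param tol Relative-change convergence tolerance on \eqn{\alpha} and
#'   \eqn{\beta} (default 1e-6).
#' @param max_iter Maximum evidence-maximization iterations (default 300).
#' @param init Initial value used for both precisions (default 1).
#' @return A \code{ridge_model} with elements \code{dgG} (named contribution
#'   vector, kJ/mol), \code{alpha}, \code{beta}, \code{lambda}, \code{S_N}
#'   (posterior covariance), \code{moiety_index}, fit diagnostics and
#'   toolkit metadata.
#' @export
fit_bayesian_ridge <- function(train, y = NULL, alpha = NULL, beta = NULL,
                               tol = 1e-6, max_iter = 300, init = 1) {
  radii <- NULL; stereo <- NULL
  if (is.matrix(train)) {
    X <- train
  } else {
    d <- as_design(train); X <- d$X; y <- d$y
    radii <- train$radii; stereo <- train$stereo
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2) mt_error("at least 2 reactions are required", "mt_input_error")
  Xty <- drop(crossprod(X, y))
  eg <- eigen(crossprod(X), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  # directions in the numerical null space carry no data: their projection of
  # X'y is zero in exact arithmetic, so zero them rather than amplify noise
  ev[ev < max(ev, 0) * 1e-12] <- 0
  Vt_Xty <- drop(crossprod(eg$vectors, Xty))
  Vt_Xty[ev == 0] <- 0

  post_mean <- function(a, b) {
    drop(eg$vectors %*% (b * Vt_Xty / (a + b * ev)))
  }

  fixed <- !is.null(alpha) && !is.null(beta)
  if (!fixed) {
    a <- init; b <- init
    converged <- FALSE
    iter <- 0
    clamp <- function(x) min(max(x, 1e-12), 1e12)
    while (iter < max_iter) {
      iter <- iter + 1
      m <- post_mean(a, b)
      gamma <- sum(b * ev / (a + b * ev))
      rss <- sum((y - drop(X %*% m))^2)
      a_new <- clamp(gamma / max(sum(m^2), 1e-300))
      b_new <- clamp(max(n - gamma, 1e-12) / max(rss, 1e-300))
      if (abs(a_new - a) <= tol * abs(a) + 1e-15 &&
          abs(b_new - b) <= tol * abs(b) + 1e-15) {
        a <- a_new; b <- b_new; converged <- TRUE
        break
      }
      a <- a_new; b <- b_new
    }
    if (!converged) {
      mt_error(sprintf(
        "evidence maximization did not converge in %d iterations (alpha=%.3g, beta=%.3g)",
        max_iter, a, b), "mt_convergence_error")
    }
    alpha <- a; beta <- b
    n_iter <- iter
  } else {
    n_iter <- 0L
  }
  dgG <- post_mean(alpha, beta)
  names(dgG) <- colnames(X)
  S_N <- eg$vectors %*% (t(eg$vectors) / (alpha + beta * ev))
  dimnames(S_N) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% dgG)
  tk <- tryCatch(mt_toolkit(), error = function(e) list(name = NA, version = NA))
  structure(list(
    dgG = dgG, alpha = alpha, beta = beta, lambda = alpha / beta,
    S_N = S_N, moiety_index = colnames(X),
    n_obs = n, n_moieties = p, n_iter = n_iter,
    mse = mean((y - fitted)^2),
    radii = radii, stereo = stereo,
    toolkit = tk$name, toolkit_version = tk$version
  ), class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf(
    "<Bayesian ridge model: %d moieties, %d observations>\n  alpha %.4g  beta %.4g  lambda %.4g  prior sd %.2f kJ/mol  training MSE %.3f (kJ/mol)^2\n",
    x$n_moieties, x$n_obs, x$alpha, x$beta, x$lambda, 1 / sqrt(x$alpha), x$mse))
  invisible(x)
}

#' Posterior predictive mean and standard deviation for a moiety-change
#' vector
#'
#' The predictive distribution for a reaction with change vector \eqn{x} is
#' Gaussian with mean \eqn{x \cdot \Delta_g G^\circ} and variance
#' \eqn{1/\beta + x^T S_N x}. Moieties absent from the training data
#' contribute 0 to the mean and their prior variance \eqn{x_g^2/\alpha} to
#' the variance, so coverage is never lost -- unseen chemistry simply widens
#' the interval.
#'
#' @param model A \code{ridge_model}.
#' @param x Named numeric moiety-change vector (names matched against the
#'   model's moiety index; unmatched names are the unseen moieties).
#' @return List with \code{mean}, \code{sd} (both kJ/mol) and
#'   \code{unseen_moieties}.
#' @export
predict_mean_std <- function(model, x) {
  stopifnot(inherits(model, "ridge_model"))
  if (is.null(names(x))) {
    if (length(x) != model$n_moieties) {
      mt_error("unnamed x must have one entry per model moiety", "mt_input_error")
    }
    names(x) <- model$moiety_index
  }
  x <- x[x != 0]
  seen <- intersect(names(x), model$moiety_index)
  unseen <- setdiff(names(x), model$moiety_index)
  xs <- x[seen]
  mu <- if (length(seen)) sum(xs * model$dgG[seen]) else 0
  v <- 1 / model$beta
  if (length(seen)) {
    v <- v + drop(t(xs) %*% model$S_N[seen, seen, drop = FALSE] %*% xs)
  }
  if (length(unseen)) v <- v + sum(x[unseen]^2) / model$alpha
  list(mean = mu, sd = sqrt(v), unseen_moieties = unseen)
}

#' Which moiety contributions are identifiable from a design matrix?
#'
#' A contribution is identifiable when its coordinate axis lies in the row
#' space of \eqn{X = S^T G}; contributions involved in exact counting
#' identities (or never exercised by the reactions) are only determined up
#' to the null space and are pinned down by the prior instead of the data.
#'
#' @param X Design matrix (reactions x moieties).
#' @param tol Relative singular-value threshold for the rank (default
#'   1e-8).
#' @return Named logical vector, one entry per column of \code{X}.
#' @export
identifiable_moieties <- function(X, tol = 1e-8) {
  sv <- svd(X)
  r <- sum(sv$d > tol * max(sv$d))
  V <- sv$v[, seq_len(r), drop = FALSE]
  score <- rowSums(V^2)
  stats::setNames(score > 1 - 1e-6, colnames(X))
}

#' Leave-one-out cross-validation over reactions
#'
#' For each held-out reaction the model is refitted on the remaining
#' reactions (hyperparameters re-estimated for the ridge model unless fixed
#' precisions are given) and the absolute prediction error recorded. A
#' subsampled mode (\code{every} > 1) evaluates every k-th reaction only and
#' is flagged in the result.
#'
#' @param train A \code{\link{training_set}}.
#' @param model_kind \code{"linear"} (Bayesian ridge) or \code{"mlp"}.
#' @param every Evaluate every \code{every}-th reaction (1 = full LOOCV).
#' @param seed Seed forwarded to \code{\link{fit_mlp}} refits.
#' @param ... Passed to the fitting function.
#' @return List with \code{abs_errors} (named by reaction index),
#'   \code{median_mae}, \code{indices} and \code{subsampled}.
#' @export
loocv <- function(train, model_kind = c("linear", "mlp"), every = 1L,
                  seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  d <- as_design(train)
  n <- nrow(d$X)
  if (n < 3) mt_error("LOOCV needs at least 3 reactions", "mt_input_error")
  idx <- seq(1L, n, by = as.integer(every))
  errs <- vapply(idx, function(j) {
    Xj <- d$X[-j, , drop = FALSE]
    yj <- d$y[-j]
    pred <- if (model_kind == "linear") {
      fit <- fit_bayesian_ridge(Xj, yj, ...)
      predict_mean_std(fit, d$X[j, ])$mean
    } else {
      fit <- fit_mlp(Xj, yj, seed = seed, ...)
      predict(fit, d$X[j, , drop = FALSE])
    }
    abs(d$y[j] - pred)
  }, numeric(1))
  list(abs_errors = stats::setNames(errs, idx), median_mae = stats::median(errs),
       indices = idx, subsampled = every > 1)
}
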