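# Single-hidden-layer perceptron with rectified-linear activation, trained by
# L-BFGS on the mean squared error. Implemented directly (forward pass +
# analytic gradients + stats::optim) so the architecture matches the
# reference nonlinear model exactly: one hidden layer, ReLU, L-BFGS.

mlp_unpack <- function(theta, p, h) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  w2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_loss_grad <- function(theta, X, y, p, h) {
  par <- mlp_unpack(theta, p, h)
  n <- nrow(X)
  Z <- sweep(X %*% par$W1, 2, par$b1, "+")
  A <- pmax(Z, 0)
  yhat <- drop(A %*% par$w2) + par$b2
  r <- yhat - y
  loss <- mean(r^2)
  # gradients of mean((yhat-y)^2)
  gy <- 2 * r / n                         # n
  g_w2 <- drop(crossprod(A, gy))          # h
  g_b2 <- sum(gy)
  GA <- outer(gy, par$w2)                 # n x h
  GZ <- GA * (Z > 0)
  g_W1 <- crossprod(X, GZ)                # p x h
  g_b1 <- colSums(GZ)
  list(value = loss, grad = c(as.numeric(g_W1), g_b1, g_w2, g_b2))
}

#' Fit the nonlinear (neural network) moiety-contribution model
#'
#' A feed-forward perceptron with a single hidden layer of
#' rectified-linear units maps the moiety-change vector to the reaction
#' Gibbs energy; weights are trained by L-BFGS minimizing the mean squared
#' error. The fit is deterministic given \code{seed} (which fixes the weight
#' initialization).
#'
#' @param train A \code{\link{training_set}} or a design matrix \code{X}.
#' @param y Observations when \code{train} is a matrix.
#' @param seed Integer seed for weight initialization (required:
#'   reproducibility contract).
#' @param hidden Number of hidden units (default 100).
#' @param maxit Maximum L-BFGS iterations (default 500).
#' @return An \code{mlp_model} with the layer weights, the seed, and the
#'   final training loss; non-convergence produces a warning, not an error.
#' @export
fit_mlp <- function(train, y = NULL, seed, hidden = 100L, maxit = 500L) {
  if (is.matrix(train)) X <- train
  else { d <- as_design(train); X <- d$X; y <- d$y }
  if (missing(seed)) mt_error("fit_mlp requires an explicit seed", "mt_input_error")
  p <- ncol(X); h <- as.integer(hidden)
  theta0 <- withr::with_seed(as.integer(seed), {
    c(stats::rnorm(p * h, sd = sqrt(2 / max(p, 1))),
      rep(0, h),
      stats::rnorm(h, sd = sqrt(2 / h)),
      0)
  })
  fit <- stats::optim(theta0, fn = function(th) mlp_loss_grad(th, X, y, p, h)$value,
                      gr = function(th) mlp_loss_grad(th, X, y, p, h)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxit)))
  if (fit$convergence != 0) {
    warning("MLP optimizer did not report convergence (code ", fit$convergence,
            "); final loss ", signif(fit$value, 6))
  }
  par <- mlp_unpack(fit$par, p, h)
  structure(list(W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
                 moiety_index = colnames(X), seed = as.integer(seed),
                 hidden = h, loss = fit$value,
                 converged = fit$convergence == 0),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (!is.null(object$moiety_index) && !is.null(colnames(X))) {
    full <- matrix(0, nrow(X), length(object$moiety_index),
                   dimnames = list(NULL, object$moiety_index))
    common <- intersect(colnames(X), object$moiety_index)
    full[, common] <- X[, common, drop = FALSE]
    X <- full
  }
  A <- pmax(sweep(X %*% object$W1, 2, object$b1, "+"), 0)
  drop(A %*% object$w2) + object$b2
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<MLP model: %d inputs, %d ReLU hidden units; seed %d; training MSE %.4g>\n",
              length(x$moiety_index), x$hidden, x$seed, x$loss))
  invisible(x)
}
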