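#' Ridge-penalized logistic regression
#'
#' Fits a logistic regression with an L2 penalty on the coefficients,
#' minimizing the penalized negative log-likelihood
#' `-l(b0, beta) + (lambda/2) * ||beta||^2` with an unpenalized intercept.
#' Predictor columns are standardized internally to mean 0 / sd 1 (dummy
#' columns included) and the standardization parameters are stored with the
#' model, so prediction on new data applies the training-set scaling only.
#' The solver is a damped Newton iteration run to a gradient norm below
#' `tol`; a quadratic penalty with `lambda > 0` makes the problem strictly
#' convex in `beta`.
#'
#' @param X numeric matrix (n x p).
#' @param y binary labels (0/1).
#' @param lambda positive ridge penalty (on the standardized scale).
#' @param tol convergence tolerance on the Euclidean norm of the penalized
#'   gradient, default 1e-6.
#' @param max_iter maximum Newton iterations, default 200.
#' @param init optional warm start: list with `intercept` and `beta`
#'   (standardized scale).
#' @return An object of class `ridge_logistic`: `intercept` and `beta` on the
#'   standardized scale, `lambda`, `center`/`scale` (per-column mean and sd of
#'   the training data), convergence diagnostics.
#' @export
fit_ridge_logistic <- function(X, y, lambda, tol = 1e-6, max_iter = 200L, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1  # constant columns stay at coefficient 0
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")

  b0 <- if (!is.null(init)) init$intercept else {
    pr <- mean(y); log(max(pr, 1e-8) / max(1 - pr, 1e-8))
  }
  beta <- if (!is.null(init)) init$beta else numeric(p)

  pen_nll <- function(b0, beta) {
    eta <- drop(b0 + Z %*% beta)
    # numerically stable -loglik: log(1 + exp(eta)) - y*eta
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      lambda / 2 * sum(beta^2)
  }

  f <- pen_nll(b0, beta)
  converged <- FALSE
  gnorm <- NA_real_
  for (it in seq_len(max_iter)) {
    eta <- drop(b0 + Z %*% beta)
    prob <- stats::plogis(eta)
    r <- prob - y
    g <- c(sum(r), drop(crossprod(Z, r)) + lambda * beta)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) { converged <- TRUE; break }
    w <- pmax(prob * (1 - prob), 1e-10)
    Zw <- Z * w
    H <- matrix(0, p + 1L, p + 1L)
    H[1, 1] <- sum(w)
    H[1, -1] <- H[-1, 1] <- colSums(Zw)
    H[-1, -1] <- crossprod(Z, Zw) + diag(lambda, p)
    step <- tryCatch(drop(chol2inv(chol(H)) %*% g),
                     error = function(e) drop(solve(H + diag(1e-8, p + 1L), g)))
    # damped update: halve the step until the penalized NLL decreases
    t_sz <- 1
    repeat {
      b0_new <- b0 - t_sz * step[1]
      beta_new <- beta - t_sz * step[-1]
      f_new <- pen_nll(b0_new, beta_new)
      if (f_new <= f + 1e-12 || t_sz < 1e-8) break
      t_sz <- t_sz / 2
    }
    b0 <- b0_new; beta <- beta_new; f <- f_new
  }
  if (!converged) {
    # final gradient check (the loop may exit at max_iter with a tiny gradient)
    eta <- drop(b0 + Z %*% beta)
    r <- stats::plogis(eta) - y
    g <- c(sum(r), drop(crossprod(Z, r)) + lambda * beta)
    gnorm <- sqrt(sum(g^2))
    if (gnorm >= tol)
      stop(sprintf(paste0("ridge logistic fit did not converge: gradient norm %.3e ",
                          "after %d iterations (lambda = %.3g, n = %d, p = %d)"),
                   gnorm, max_iter, lambda, n, p))
    converged <- TRUE
  }
  structure(list(intercept = b0,
                 beta = stats::setNames(beta, colnames(X)),
                 lambda = lambda, center = mu, scale = sdv,
                 converged = converged, n_iter = it, grad_norm = gnorm),
            class = "ridge_logistic")
}

#' Predict from a ridge logistic model
#'
#' @param object a `ridge_logistic` model.
#' @param newX numeric matrix with the same columns as the training matrix.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @export
predict.ridge_logistic <- function(object, newX, type = c("response", "link"), ...) {
  type <- match.arg(type)
  newX <- as.matrix(newX)
  Z <- sweep(sweep(newX, 2, object$center, "-"), 2, object$scale, "/")
  eta <- drop(object$intercept + Z %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat(sprintf("ridge_logistic: p = %d, lambda = %.4g, %d Newton iterations (|grad| = %.2e)\n",
              length(x$beta), x$lambda, x$n_iter, x$grad_norm))
  invisible(x)
}

#' Normalized dose-feature importance of a ridge model
#'
#' Rescales the standardized ridge coefficients of the dose features so that
#' the largest absolute dose coefficient maps to +/-100, for spatial
#' importance maps. Clinical coefficients are excluded from the normalization
#' and returned separately, unnormalized.
#'
#' @param model a `ridge_logistic` fit on the 214-column design matrix (or
#'   any matrix containing dose-feature columns).
#' @param dose_features names of the dose-feature columns, default the
#'   canonical 198.
#' @return Named numeric vector of importances in [-100, 100] over the dose
#'   features, with the unnormalized clinical coefficients as attribute
#'   `clinical`.
#' @export
normalized_importance <- function(model, dose_features = dose_feature_names()) {
  stopifnot(inherits(model, "ridge_logistic"))
  nm <- names(model$beta)
  dose_idx <- nm %in% dose_features
  b <- model$beta[dose_idx]
  mx <- max(abs(b))
  imp <- if (mx == 0) b * 0 else 100 * b / mx
  attr(imp, "clinical") <- model$beta[!dose_idx]
  imp
}
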