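# L2-penalized logistic regression by iteratively reweighted least squares.
# Objective: -(1/n) loglik + (lambda/2) ||beta||^2 (intercept unpenalized).
# With ridge curvature the Newton system is always positive definite, so the
# fit converges for any lambda > 0, including (near-)separable data.

#' Fit ridge logistic regression
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param lambda L2 penalty on the coefficients (not the intercept).
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `hk_ridge_lr` with `coef` (intercept first).
#' @export
ridge_logistic_fit <- function(x, y, lambda, max_iter = 100, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xd <- cbind(1, x)
  beta <- numeric(p + 1)
  pen <- diag(c(0, rep(lambda, p)))
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(xd, mu - y)) / n + drop(pen %*% beta)
    hess <- crossprod(xd * w, xd) / n + pen
    step <- solve(hess + diag(1e-12, p + 1), grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  structure(list(coef = beta, lambda = lambda, iters = it),
            class = "hk_ridge_lr")
}

#' Predict probabilities from a ridge logistic fit
#' @param fit an `hk_ridge_lr`.
#' @param x feature matrix.
#' @return probabilities in `[0, 1]`.
#' @export
ridge_logistic_predict <- function(fit, x) {
  as.numeric(stats::plogis(drop(cbind(1, as.matrix(x)) %*% fit$coef)))
}
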