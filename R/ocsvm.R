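# One-class support vector machine, fitted by solving the dual quadratic
# program directly:
#
#   minimize   1/2 * t(alpha) K alpha
#   subject to 0 <= alpha_i <= 1/(nu * n),  sum(alpha) = 1
#
# with decision function f(x) = sum_i alpha_i k(x_i, x) - rho, positive
# inside the learned frontier. nu upper-bounds the training outlier
# fraction and lower-bounds the support-vector fraction. The solver is an
# accelerated projected-gradient (FISTA) scheme; problem sizes in this
# package (a few hundred training samples) converge in milliseconds.

kernel_matrix <- function(a, b, kernel, gamma = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (kernel == "linear") return(tcrossprod(a, b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Euclidean projection onto {0 <= a <= C, sum(a) = 1} by bisection on the
# shift tau in a_i = clamp(v_i - tau, 0, C); the sum is decreasing in tau.
project_capped_simplex <- function(v, C) {
  lo <- min(v) - C - 1
  hi <- max(v)
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    if (sum(pmin(pmax(v - mid, 0), C)) > 1) lo <- mid else hi <- mid
  }
  pmin(pmax(v - (lo + hi) / 2, 0), C)
}

#' Fit a one-class SVM on (standardized) healthy samples
#'
#' @param x numeric matrix of training samples (standardize first; the
#'   screening pipeline does this per fold).
#' @param kernel `"rbf"` or `"linear"`.
#' @param nu in `(0, 1]`: upper bound on the training outlier fraction.
#' @param gamma RBF kernel width parameter (ignored for linear).
#' @param max_iter,tol solver controls.
#' @return an object of class `ocsvm` with elements `x` (support inputs),
#'   `alpha`, `rho`, `kernel`, `nu`, `gamma`.
#' @export
ocsvm_fit <- function(x, kernel = c("rbf", "linear"), nu = 0.1,
                      gamma = 1 / ncol(x), max_iter = 4000L, tol = 1e-10) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("one-class SVM needs at least 2 training samples")
  stopifnot(nu > 0, nu <= 1)
  K <- kernel_matrix(x, x, kernel, gamma)
  C <- 1 / (nu * n)
  alpha <- as.numeric(ocsvm_solve_cpp(K, C, as.integer(max_iter), tol))
  g <- as.numeric(K %*% alpha)
  eps <- C * 1e-6
  margin <- which(alpha > eps & alpha < C - eps)
  rho <- if (length(margin)) {
    mean(g[margin])
  } else {
    # no margin SVs: any rho between the bound-support maximum and the
    # zero-alpha minimum satisfies the KKT conditions; take the midpoint
    lo <- suppressWarnings(max(g[alpha >= C - eps]))
    hi <- suppressWarnings(min(g[alpha <= eps]))
    if (!is.finite(lo)) hi else if (!is.finite(hi)) lo else (lo + hi) / 2
  }
  # squared RKHS norm of the decision functional; ~0 means the fitted
  # decision function is constant (e.g. a linear kernel on data whose
  # convex hull contains the origin) and the model carries no information
  w_norm2 <- sum(alpha * g)
  structure(list(x = x, alpha = alpha, rho = rho, kernel = kernel,
                 nu = nu, gamma = if (kernel == "rbf") gamma else NULL,
                 w_norm2 = w_norm2, kdiag_mean = mean(diag(K))),
            class = "ocsvm")
}

#' One-class SVM decision values
#'
#' `ocsvm_decision()` returns the native decision value
#' `f(x) = sum_i alpha_i k(x_i, x) - rho`, positive inside the frontier.
#' `ocsvm_score()` returns the pipeline-facing oriented score `-f(x)`, so
#' that larger values mean more outlier-like; the Platt sigmoid is fitted on
#' this orientation.
#'
#' @param object an `ocsvm` fit.
#' @param newdata numeric matrix in the same (standardized) space.
#' @return numeric vector.
#' @export
ocsvm_decision <- function(object, newdata) {
  K <- kernel_matrix(as.matrix(newdata), object$x, object$kernel, object$gamma)
  as.numeric(K %*% object$alpha) - object$rho
}

#' @rdname ocsvm_decision
#' @export
ocsvm_score <- function(object, newdata) {
  -ocsvm_decision(object, newdata)
}

#' Is a fitted one-class SVM degenerate (constant decision function)?
#'
#' A one-class SVM whose decision functional has (near-)zero RKHS norm
#' assigns essentially the same score to every input; it cannot separate
#' anything and its scores cannot be Platt-calibrated. This happens
#' structurally for the linear kernel on standardized (training-centered)
#' data, where the origin lies inside the convex hull of the training
#' points and the dual optimum is `w = 0`.
#'
#' @param object an `ocsvm` fit.
#' @param tol relative tolerance on `||w||^2 / mean(diag(K))`.
#' @return logical.
#' @export
ocsvm_is_degenerate <- function(object, tol = 1e-6) {
  object$w_norm2 < tol * max(object$kdiag_mean, .Machine$double.eps)
}
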