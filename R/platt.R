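# Platt scaling: a univariate ridge-penalized logistic regression mapping
# raw classifier scores to calibrated outlier probabilities, with the
# penalty strength chosen by cross-validation on the calibration set.

# Ridge logistic regression of y on a single score, intercept unpenalized.
# Newton/IRLS; lambda > 0 keeps the slope finite on separable data.
ridge_logistic_1d <- function(s, y, lambda) {
  beta <- c(0, 0)  # (intercept, slope)
  X <- cbind(1, s)
  for (it in 1:100) {
    eta <- as.numeric(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- as.numeric(crossprod(X, p - y)) + c(0, lambda * beta[2])
    H <- crossprod(X * w, X) + diag(c(1e-12, lambda))
    step <- solve(H, grad)
    beta_new <- beta - step
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

log_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Stratified fold ids ensuring each class is spread over the folds.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    id <- integer(length(y))
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      id[ix] <- rep_len(seq_len(k), length(ix))
    }
    id
  })
}

#' Fit a Platt calibration sigmoid to classifier scores
#'
#' Fits `p(outlier | score) = plogis(intercept + slope * score)` by ridge
#' logistic regression, with the L2 penalty chosen from `lambda_grid` by
#' `cv_folds`-fold cross-validated log loss on the calibration set. Scores
#' must be oriented so that larger = more outlier-like (see
#' [ocsvm_score()]), giving a positive slope and a probability strictly
#' increasing in the score.
#'
#' The score is standardized internally before fitting so that the ridge
#' penalty is invariant to the (arbitrary) scale of a decision function;
#' the returned `intercept`/`slope` are re-expressed on the raw-score
#' scale.
#'
#' @param scores numeric vector of raw scores.
#' @param labels 0/1 vector (healthy = 0, outlier = 1); both classes must be
#'   present.
#' @param cv_folds folds for the penalty search (default 5; capped at the
#'   minority class count).
#' @param lambda_grid candidate L2 strengths.
#' @param seed seed for fold assignment.
#' @return a list of class `platt_calibration`: `intercept`, `slope`,
#'   `lambda`.
#' @export
platt_fit <- function(scores, labels, cv_folds = 5L,
                      lambda_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    stop("calibration set contains a single class; both healthy and outlier ",
         "labels are required (are pathology validation subjects missing?)")
  }
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  ctr <- mean(scores)
  scl <- stats::sd(scores)
  if (!is.finite(scl) || scl < 1e-12) scl <- 1
  s <- (scores - ctr) / scl
  k <- max(2L, min(cv_folds, min(table(y))))
  if (k >= 2 && length(y) >= 2 * k) {
    fold_id <- stratified_folds(y, k, seed)
    cv_loss <- vapply(lambda_grid, function(lam) {
      mean(vapply(seq_len(k), function(f) {
        tr <- fold_id != f
        b <- ridge_logistic_1d(s[tr], y[tr], lam)
        log_loss(plogis(b[1] + b[2] * s[!tr]), y[!tr])
      }, numeric(1)))
    }, numeric(1))
    lambda <- lambda_grid[which.min(cv_loss)]
  } else {
    lambda <- 1
  }
  beta <- ridge_logistic_1d(s, y, lambda)
  # map back to the raw-score scale
  structure(list(intercept = beta[1] - beta[2] * ctr / scl,
                 slope = beta[2] / scl, lambda = lambda),
            class = "platt_calibration")
}

#' Apply a Platt calibration to raw scores
#' @param calibration a `platt_calibration`.
#' @param scores numeric vector.
#' @return calibrated probabilities in `(0, 1)`.
#' @export
platt_predict <- function(calibration, scores) {
  plogis(calibration$intercept + calibration$slope * scores)
}
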