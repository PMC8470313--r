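# The solver is checked against the Karush-Kuhn-Tucker conditions of the
# one-class SVM dual, which characterize the optimum independently of the
# optimization path:
#   alpha_i = 0          =>  (K alpha)_i >= rho
#   alpha_i = C          =>  (K alpha)_i <= rho
#   0 < alpha_i < C      =>  (K alpha)_i  = rho
# together with 0 <= alpha <= C and sum(alpha) = 1.
kkt_violation <- function(fit) {
  K <- posturescreen:::kernel_matrix(fit$x, fit$x, fit$kernel, fit$gamma)
  g <- as.numeric(K %*% fit$alpha)
  C <- 1 / (fit$nu * nrow(fit$x))
  eps <- C * 1e-4
  at0 <- fit$alpha <= eps
  atC <- fit$alpha >= C - eps
  mid <- !at0 & !atC
  scale <- max(abs(g))
  max(c(0,
        (fit$rho - g[at0]) / scale,    # should be <= 0
        (g[atC] - fit$rho) / scale,    # should be <= 0
        abs(g[mid] - fit$rho) / scale))
}

test_that("dual solution satisfies the KKT conditions", {
  set.seed(3)
  x <- matrix(rnorm(80 * 5), 80)
  for (cfg in list(list("rbf", 0.1, 0.2), list("rbf", 0.5, 0.05),
                   list("linear", 0.2, NULL))) {
    fit <- ocsvm_fit(x + 2, kernel = cfg[[1]], nu = cfg[[2]],
                     gamma = if (is.null(cfg[[3]])) 0.2 else cfg[[3]])
    expect_equal(sum(fit$alpha), 1, tolerance = 1e-8)
    expect_true(all(fit$alpha >= -1e-12))
    expect_true(all(fit$alpha <= 1 / (fit$nu * 80) + 1e-12))
    expect_lt(kkt_violation(fit), 5e-3)
  }
})

test_that("nu bounds the training outlier fraction (nu-property)", {
  set.seed(5)
  x <- matrix(rnorm(200 * 8), 200)
  fit <- ocsvm_fit(x, kernel = "rbf", nu = 0.5, gamma = 0.1)
  frac_out <- mean(ocsvm_decision(fit, x) < -1e-8)
  expect_gt(frac_out, 0.4)   # ~50% +/- 10 pp at nu = 0.5
  expect_lt(frac_out, 0.6)
  # support-vector fraction >= nu
  expect_gte(mean(fit$alpha > 1e-10), 0.5 - 0.02)
})

test_that("score orientation: far points score as outliers", {
  set.seed(7)
  x <- matrix(rnorm(100 * 6), 100)
  fit <- ocsvm_fit(x, kernel = "rbf", nu = 0.1, gamma = 0.1)
  far <- matrix(rnorm(20 * 6, mean = 8), 20)
  expect_gt(min(ocsvm_score(fit, far)), median(ocsvm_score(fit, x)))
  # larger score = more outlier-like; decision and score are negatives
  expect_equal(ocsvm_score(fit, far), -ocsvm_decision(fit, far))
})

test_that("fits are deterministic and reject degenerate input", {
  set.seed(9)
  x <- matrix(rnorm(50 * 4), 50)
  f1 <- ocsvm_fit(x, "rbf", nu = 0.2, gamma = 0.3)
  f2 <- ocsvm_fit(x, "rbf", nu = 0.2, gamma = 0.3)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$rho, f2$rho)
  expect_error(ocsvm_fit(x[1, , drop = FALSE], "rbf"), "at least 2")
})

test_that("linear kernel on centered data is flagged as degenerate", {
  set.seed(11)
  x <- scale(matrix(rnorm(100 * 10), 100))  # origin inside the hull
  fit_lin <- ocsvm_fit(x, "linear", nu = 0.1)
  expect_true(ocsvm_is_degenerate(fit_lin))
  # shifted away from the origin the linear one-class SVM is meaningful
  fit_shift <- ocsvm_fit(x + 5, "linear", nu = 0.1)
  expect_false(ocsvm_is_degenerate(fit_shift))
  # RBF kernels are not affected by centering
  fit_rbf <- ocsvm_fit(x, "rbf", nu = 0.1, gamma = 0.1)
  expect_false(ocsvm_is_degenerate(fit_rbf))
})
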