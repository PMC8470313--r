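test_that("healthy generator degenerate noise cases", {
  co0 <- generate_healthy_cohort(healthy_model_spec(
    n_subjects = 3, measurements_per_subject = 4,
    within_subject_sd = 0, seed = 5))
  x <- cohort_matrix(co0)
  for (sid in unique(co0$subject_id)) {
    xs <- x[co0$subject_id == sid, ]
    expect_lt(max(abs(sweep(xs, 2, xs[1, ]))), 1e-12)
  }

  spec <- healthy_model_spec(n_subjects = 3, measurements_per_subject = 2,
                             between_subject_sd = 0, within_subject_sd = 0,
                             seed = 5)
  flat <- cohort_matrix(generate_healthy_cohort(spec))
  expect_lt(max(abs(sweep(flat, 2, spec$population_mean))), 1e-12)
})

test_that("empirical variance components match the model spec within 10%", {
  co <- generate_healthy_cohort(healthy_model_spec(
    n_subjects = 200, measurements_per_subject = 5, seed = 31))
  x <- cohort_matrix(co)
  sid <- co$subject_id
  within <- mean(vapply(split(seq_len(nrow(x)), sid), function(ix) {
    mean(apply(x[ix, ], 2, var))
  }, numeric(1)))
  subj_means <- do.call(rbind, lapply(split(seq_len(nrow(x)), sid),
                                      function(ix) colMeans(x[ix, ])))
  between <- mean(apply(subj_means, 2, var)) - within / 5
  expect_lt(abs(within - 1) / 1, 0.10)   # within_subject_sd = 1 -> var 1
  expect_lt(abs(between - 9) / 9, 0.10)  # between_subject_sd = 3 -> var 9
})

test_that("outlier cleaning removes the requested fraction and drops shifted subjects", {
  co <- make_healthy(n_subjects = 10, m = 10, seed = 17)
  expect_identical(remove_healthy_outliers(co, contamination = 0, seed = 1),
                   co, ignore_attr = TRUE)

  # 100 samples, contamination 0.2 -> exactly 20 removed
  cleaned <- remove_healthy_outliers(co, contamination = 0.2, min_samples = 5,
                                     seed = 2)
  log2 <- attr(cleaned, "removal_log")
  expect_equal(nrow(log2$removed), 20L)
  # every surviving subject keeps at least min_samples measurements
  expect_true(all(table(cleaned$subject_id) >= 5))

  # planted outlier subject: +10 SD on every feature
  df <- as.data.frame(co)
  shift <- df$subject_id == "H01"
  df[shift, feat_names] <- df[shift, feat_names] + 10 * 3
  planted <- as_posture_cohort(df)
  cleaned2 <- remove_healthy_outliers(planted, contamination = 0.1,
                                      min_samples = 10, seed = 3)
  expect_true("H01" %in% attr(cleaned2, "removal_log")$dropped_subjects)
  expect_false("H01" %in% cleaned2$subject_id)
})

test_that("the realized removal count matches a 900-sample cohort cleaned at 150/900", {
  co <- make_healthy(n_subjects = 25, m = 36, seed = 19)
  expect_equal(nrow(co), 900L)
  cleaned <- remove_healthy_outliers(co, contamination = 150 / 900, seed = 4)
  expect_equal(nrow(attr(cleaned, "removal_log")$removed), 150L)
})

test_that("standardized PCA matches a brute-force eigendecomposition", {
  set.seed(23)
  x <- matrix(rnorm(10 * 55), 10)
  colnames(x) <- feat_names
  basis <- fit_posture_pca(x)
  z <- scale(x)
  ev <- eigen(crossprod(z) / (nrow(x) - 1), symmetric = TRUE)
  k <- 5  # rank-limited toy set: compare the leading components
  expect_equal(basis$explained_variance[1:k], ev$values[1:k], tolerance = 1e-8)
  for (j in 1:k) {
    expect_gt(abs(sum(basis$components[, j] * ev$vectors[, j])), 1 - 1e-8)
  }
  # explained variances sum to the total standardized variance
  expect_equal(sum(basis$explained_variance), sum(apply(z, 2, var)),
               tolerance = 1e-6)
  # orthonormality
  g <- crossprod(basis$components)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
})

test_that("PCA finds a single dominant axis and rejects constant features", {
  set.seed(11)
  dir <- rnorm(55); dir <- dir / sqrt(sum(dir^2))
  x <- outer(rnorm(100, sd = 5), dir) + matrix(rnorm(100 * 55, sd = 0.01), 100)
  colnames(x) <- feat_names
  basis <- fit_posture_pca(x)
  # in the standardized space the dominant axis is dir rescaled by 1/sd
  dir_z <- dir / apply(x, 2, sd)
  dir_z <- dir_z / sqrt(sum(dir_z^2))
  cosine <- abs(sum(basis$components[, 1] * dir_z))
  expect_gt(cosine, 0.999)

  x2 <- x; x2[, 3] <- 1
  expect_error(fit_posture_pca(x2), "pelvic_inclination_deg")
})

test_that("forward/backward PCA maps are mutually inverse on full-rank data", {
  co <- make_healthy(n_subjects = 12, m = 6, seed = 29)  # 72 > 55 samples
  basis <- fit_posture_pca(co)
  x <- cohort_matrix(co)
  back <- pca_inverse_transform(basis, pca_transform(basis, x))
  expect_lt(max(abs(back - x)), 1e-8)
})

test_that("silhouette matches the brute-force oracle and limit cases", {
  set.seed(37)
  a <- matrix(rnorm(6), 3)
  b <- matrix(rnorm(6, mean = 2), 3)
  expect_equal(silhouette_between(a, b), silhouette_oracle(a, b),
               tolerance = 1e-12)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(c(1, 1, 1, 2, 2, 2), dist(rbind(a, b)))
    expect_equal(silhouette_between(a, b), mean(sil[, "sil_width"]),
                 tolerance = 1e-12)
  }

  tight_a <- matrix(rnorm(40, sd = 0.01), 20)
  tight_b <- matrix(rnorm(40, sd = 0.01), 20) + 100
  expect_gt(silhouette_between(tight_a, tight_b), 0.95)

  same_a <- matrix(rnorm(500 * 2), 500)
  same_b <- matrix(rnorm(500 * 2), 500)
  expect_lt(abs(silhouette_between(same_a, same_b)), 0.05)

  expect_error(silhouette_between(matrix(0, 1, 2), tight_b), "at least 2")
})

test_that("pathology classes hit their target silhouettes and sizes", {
  h <- make_healthy(n_subjects = 24, m = 10, seed = 41)
  basis <- fit_posture_pca(h)
  zh <- pca_transform(basis, h) %*% t(basis$components)  # standardized space

  centers <- c()
  for (tgt in list(list("S1", 1L, 0.49), list("S4", 4L, 0.16))) {
    cls <- generate_pathology_class(
      basis, synthetic_class_spec(tgt[[1]], tgt[[2]], tgt[[3]], seed = 53), h)
    expect_equal(nrow(cls), 240L)
    expect_equal(nrow(cohort_subjects(cls)), 24L)
    expect_equal(unique(table(cls$subject_id)), 10L, ignore_attr = TRUE)
    achieved <- attr(cls, "achieved_silhouette")
    expect_lt(abs(achieved - tgt[[3]]), 0.02)
    # attribute agrees with an external recomputation in standardized space
    zc <- sweep(sweep(cohort_matrix(cls), 2, basis$feature_means),
                2, basis$feature_sds, `/`)
    expect_equal(silhouette_between(zc, zh), achieved, tolerance = 1e-10)
    centers <- c(centers, attr(cls, "center"))
  }
  # higher target silhouette requires a larger PC offset
  expect_gt(centers[1], centers[2])

  expect_error(
    generate_pathology_class(
      basis, synthetic_class_spec("S9", 1L, 0.99, seed = 3), h,
      center_range = c(0, 0.1)),
    "not attainable")
})

test_that("per-subject sample draw is exact, seeded, and validated", {
  co <- make_healthy(n_subjects = 4, m = 12, seed = 61)
  d1 <- draw_subject_samples(co, 10, seed = 9)
  d2 <- draw_subject_samples(co, 10, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(unique(table(d1$subject_id)), 10L, ignore_attr = TRUE)
  # distinct measurement ids within subject
  expect_false(any(tapply(d1$measurement_id, d1$subject_id,
                          function(v) anyDuplicated(v) > 0)))
  # subject with exactly n samples keeps all
  d3 <- draw_subject_samples(co, 12, seed = 9)
  expect_identical(as.data.frame(d3), as.data.frame(co))
  expect_error(draw_subject_samples(co, 13, seed = 9), "fewer than 13")
})
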