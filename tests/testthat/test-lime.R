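train_stats_55 <- function(means = rep(0, 55), sds = rep(1, 55)) {
  list(means = setNames(means, feat_names), sds = setNames(sds, feat_names))
}

test_that("a constant predictor yields a degenerate all-zero explanation", {
  expect_warning(
    e <- explain_sample(function(X) rep(0.7, nrow(X)), rep(0, 55),
                        train_stats_55(), n_perturbations = 200, seed = 1),
    "constant")
  expect_length(e$effect, 0)
  expect_equal(e$fidelity, 0)
})

test_that("a planted single-feature signal is recovered with the right sign", {
  j <- 12
  fn <- function(X) plogis(2 * X[, j])
  stats <- train_stats_55()
  # instance displaced positively on the signal feature
  x_pos <- rep(0, 55); x_pos[j] <- 2
  e_pos <- explain_sample(fn, x_pos, stats, n_perturbations = 1000,
                          n_features = 5, seed = 3)
  expect_identical(e_pos$features[1], feat_names[j])
  expect_gt(e_pos$effect[1], 0)
  expect_gt(e_pos$fidelity, 0.5)
  # displaced negatively: same top feature, opposite effect direction
  x_neg <- rep(0, 55); x_neg[j] <- -2
  e_neg <- explain_sample(fn, x_neg, stats, n_perturbations = 1000,
                          n_features = 5, seed = 3)
  expect_identical(e_neg$features[1], feat_names[j])
  expect_lt(e_neg$effect[1], 0)
})

test_that("the number of reported effects is capped and seeds fix the output", {
  fn <- function(X) plogis(rowSums(X[, 1:20, drop = FALSE]) / 4)
  e10 <- explain_sample(fn, rnorm(55), train_stats_55(),
                        n_perturbations = 400, n_features = 10, seed = 5)
  expect_lte(length(e10$effect), 10)
  e_a <- explain_sample(fn, rep(1, 55), train_stats_55(),
                        n_perturbations = 400, n_features = 10, seed = 9)
  e_b <- explain_sample(fn, rep(1, 55), train_stats_55(),
                        n_perturbations = 400, n_features = 10, seed = 9)
  expect_identical(e_a, e_b)
})

test_that("subject aggregation ranks by mean absolute effect", {
  mk_expl <- function(features, effect) {
    structure(list(features = features, effect = effect, coef = effect,
                   intercept = 0, fidelity = 0.9, prediction = 0.8,
                   n_features = length(features)),
              class = "lime_explanation")
  }
  e1 <- mk_expl(feat_names[c(5, 10, 20)], c(0.5, -0.2, 0.1))
  agg_same <- aggregate_subject_explanations(list(e1, e1, e1), top_k = 3,
                                             subject_id = "s")
  expect_equal(agg_same$table$sd_effect, rep(0, 3))
  expect_identical(agg_same$table$feature[1], feat_names[5])

  # brute-force ranking oracle over random explanation sets
  set.seed(95)
  for (rep_i in 1:5) {
    feats <- sample(feat_names, 6)
    es <- lapply(1:4, function(i) mk_expl(feats, rnorm(6)))
    agg <- aggregate_subject_explanations(es, top_k = 6)
    eff_mat <- sapply(es, function(e) e$effect[match(sort(feats), feats)])
    oracle_rank <- sort(feats)[order(-abs(rowMeans(eff_mat)))]
    expect_identical(agg$table$feature, oracle_rank)
  }
  # top_k = 3 gives a triple of level labels
  expect_length(agg_same$top_features, 3)
  expect_true(all(agg_same$top_features %in% c("P", "VP", paste0("T", 1:12),
                                               paste0("L", 1:4))))
})

test_that("fold-wise explanation covers each pathology subject exactly once", {
  # moderate separation so calibrated probabilities are not saturated and
  # the local surrogate sees a gradient over the perturbations
  h <- make_healthy(n_subjects = 16, m = 6, seed = 97)
  basis <- fit_posture_pca(h)
  cls <- generate_pathology_class(
    basis, synthetic_class_spec("SX", 1, 0.40, n_subjects = 16,
                                samples_per_subject = 6, seed = 99), h)
  ex <- run_experiment(h, cls, screening_config(n_folds = 2, n_iter = 10,
                                                seed = 25,
                                                models = "one_class"))
  cohort <- cohort_rbind(h, cls)
  # a no-skill fold produces flat probabilities whose explanations warn
  # about degeneracy; that contract is asserted in its own test above
  expl <- suppressWarnings(
    explain_test_folds(ex, cohort, model_kind = "one_class",
                       n_perturbations = 300, n_features = 10, seed = 31))
  expect_setequal(names(expl), unique(cls$subject_id))
  expl2 <- suppressWarnings(
    explain_test_folds(ex, cohort, model_kind = "one_class",
                       n_perturbations = 300, n_features = 10, seed = 31))
  expect_identical(expl, expl2)
  # per-subject table covers at most the union of per-sample top-10 sets
  expect_true(all(vapply(expl, function(e) nrow(e$table) <= 55, logical(1))))

  # orientation consistency: confidently-outlying subjects have top effects
  # that sum toward the outlier class
  subj <- ex$reports$one_class$subjects
  sure <- subj$subject_id[subj$group != "healthy" &
                            subj$mean_outlier_probability > 0.9]
  expect_gt(length(sure), 0)
  sums <- vapply(sure, function(s) sum(expl[[s]]$table$mean_effect),
                 numeric(1))
  expect_gt(mean(sums > 0), 0.75)
  # fidelity is reported and positive for informative fold models; the
  # R^2 > 0.5 level is only expected for smooth near-linear predictors
  # (see the planted-oracle test), not for saturated RBF surfaces
  fid <- vapply(sure, function(s) expl[[s]]$mean_fidelity, numeric(1))
  expect_true(all(fid > 0))
})
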