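# Local surrogate-model (LIME-style) explanations of calibrated outlier
# probabilities. For one instance, perturbations are drawn from the
# training feature distribution, predicted with the black-box probability
# function, weighted by proximity to the instance, and a weighted sparse
# linear surrogate is fitted. The reported signed effect of feature j is
# the surrogate coefficient times the instance's standardized displacement,
# so positive effects push toward the outlier class and negative effects
# toward the healthy class.

weighted_ridge <- function(Z, y, w, lambda = 1) {
  sw <- sqrt(w)
  Zw <- cbind(1, Z) * sw
  yw <- y * sw
  p <- ncol(Z)
  A <- crossprod(Zw) + diag(c(1e-10, rep(lambda, p)))
  as.numeric(solve(A, crossprod(Zw, yw)))
}

#' Explain one sample's outlier probability with a local linear surrogate
#'
#' @param probability_fn function mapping a raw feature matrix (rows =
#'   samples) to outlier probabilities, e.g. built from a
#'   `calibrated_model` via [predict_proba()].
#' @param sample numeric 55-vector (raw degrees) to explain.
#' @param training_stats list with `means` and `sds` (per-feature, from the
#'   fold's training data); a `standardizer` works directly.
#' @param n_perturbations perturbations drawn from `N(means, sds^2)`
#'   (default 2000).
#' @param n_features maximum number of reported effects (default 10).
#' @param kernel_width proximity kernel width on standardized distance
#'   (default `sqrt(p) * 0.75`).
#' @param seed integer seed.
#' @return a list of class `lime_explanation`: `features`, `effect`
#'   (signed, see above), `coef`, `intercept`, `fidelity` (weighted
#'   surrogate R^2), `prediction` (probability at the instance).
#' @export
explain_sample <- function(probability_fn, sample, training_stats,
                           n_perturbations = 2000L, n_features = 10L,
                           kernel_width = NULL, seed = 1L) {
  mu <- training_stats$means
  sds <- training_stats$sds
  p <- length(mu)
  stopifnot(length(sample) == p, length(sds) == p)
  if (is.null(kernel_width)) kernel_width <- sqrt(p) * 0.75
  feat_names <- names(mu) %||% paste0("f", seq_len(p))

  z_inst <- (as.numeric(sample) - mu) / sds
  Z <- with_seed(seed, matrix(rnorm(n_perturbations * p), n_perturbations, p))
  X <- sweep(sweep(Z, 2, sds, `*`), 2, mu, `+`)
  colnames(X) <- feat_names
  phat <- as.numeric(probability_fn(X))
  stopifnot(length(phat) == n_perturbations)

  d2 <- rowSums(sweep(Z, 2, z_inst)^2)
  w <- exp(-d2 / kernel_width^2)
  # normalize to mean 1 so the ridge penalty keeps a fixed relative weight
  # regardless of how far the instance sits from the perturbation cloud
  w <- w / mean(w)
  pred_inst <- as.numeric(probability_fn(matrix(as.numeric(sample), 1,
                                                dimnames = list(NULL, feat_names))))

  if (stats::sd(phat) < 1e-12) {
    warning("probability function is constant over the perturbations; ",
            "explanation is degenerate (all effects zero)")
    return(structure(list(features = character(0), effect = numeric(0),
                          coef = numeric(0), intercept = mean(phat),
                          fidelity = 0, prediction = pred_inst,
                          n_features = as.integer(n_features)),
                     class = "lime_explanation"))
  }

  beta_full <- weighted_ridge(Z, phat, w)
  sel <- order(abs(beta_full[-1]), decreasing = TRUE)[seq_len(min(n_features, p))]
  beta <- weighted_ridge(Z[, sel, drop = FALSE], phat, w)
  yhat <- beta[1] + Z[, sel, drop = FALSE] %*% beta[-1]
  ybar <- sum(w * phat) / sum(w)
  fidelity <- 1 - sum(w * (phat - yhat)^2) / sum(w * (phat - ybar)^2)

  structure(list(features = feat_names[sel],
                 effect = as.numeric(beta[-1] * z_inst[sel]),
                 coef = as.numeric(beta[-1]),
                 intercept = beta[1],
                 fidelity = fidelity,
                 prediction = pred_inst,
                 n_features = as.integer(n_features)),
            class = "lime_explanation")
}

#' Aggregate a subject's per-sample explanations
#'
#' Computes the per-feature mean and SD of signed effects over the
#' subject's samples (features a sample did not select contribute 0) and
#' ranks features by mean absolute effect. Feature labels follow the
#' reporting convention of the field: pelvic parameters collapse to `"P"`,
#' vertebral features to their level (e.g. `"T4"`), with the plane kept in
#' `plane_label`.
#'
#' @param explanations list of `lime_explanation` objects for one subject.
#' @param top_k number of top features to report (default 3 for tabular
#'   reports; 10 is typical for plots).
#' @param subject_id optional subject identifier carried into the result.
#' @return a list of class `subject_explanation`: `subject_id`, `table`
#'   (feature, level_label, plane_label, mean_effect, sd_effect, ranked),
#'   `top_features` (level labels of the `top_k` rows), `mean_fidelity`.
#' @export
aggregate_subject_explanations <- function(explanations, top_k = 3L,
                                           subject_id = NA_character_) {
  stopifnot(length(explanations) >= 1)
  feats <- sort_c(unique(unlist(lapply(explanations, `[[`, "features"))))
  if (length(feats) == 0) {
    return(structure(list(subject_id = subject_id,
                          table = data.frame(), top_features = character(0),
                          mean_fidelity = 0),
                     class = "subject_explanation"))
  }
  eff <- vapply(explanations, function(e) {
    v <- setNames(numeric(length(feats)), feats)
    v[e$features] <- e$effect
    v
  }, numeric(length(feats)))
  eff <- matrix(eff, nrow = length(feats))
  sch <- posture_schema()
  idx <- match(feats, sch$name)
  tab <- data.frame(
    feature = feats,
    level_label = ifelse(sch$plane[idx] == "pelvic", "P", sch$level[idx]),
    plane_label = sch$plane[idx],
    mean_effect = rowMeans(eff),
    sd_effect = apply(eff, 1, stats::sd),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-abs(tab$mean_effect)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    subject_id = subject_id,
    table = tab,
    top_features = head(tab$level_label, top_k),
    mean_fidelity = mean(vapply(explanations, `[[`, numeric(1), "fidelity"))
  ), class = "subject_explanation")
}

#' Explain every test sample of a screening experiment
#'
#' Each fold's own calibrated model explains the predictions of that fold's
#' test subjects, so every subject is explained exactly once, by a model
#' that never saw it. The subject's repeated measurements are aggregated
#' with [aggregate_subject_explanations()].
#'
#' @param experiment a `screening_experiment` from [run_experiment()].
#' @param cohort the combined cohort (healthy + pathology) the experiment
#'   was run on, or `cohort_rbind()` of the two inputs.
#' @param model_kind `"one_class"` or `"binary"`.
#' @param groups which group labels to explain (default: all non-healthy).
#' @param n_perturbations,n_features,top_k,seed explainer controls.
#' @return named list of `subject_explanation` objects (one per explained
#'   subject).
#' @export
explain_test_folds <- function(experiment, cohort,
                               model_kind = c("one_class", "binary"),
                               groups = NULL, n_perturbations = 2000L,
                               n_features = 10L, top_k = 3L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  sub <- cohort_subjects(cohort)
  if (is.null(groups)) groups <- setdiff(unique(sub$group), "healthy")
  out <- list()
  for (f in seq_along(experiment$fold_models)) {
    fm <- experiment$fold_models[[f]]
    model <- fm[[model_kind]]
    if (is.null(model)) stop("fold ", f, " has no fitted ", model_kind, " model")
    stats_f <- list(means = fm$standardizer$means, sds = fm$standardizer$sds)
    prob_fn <- function(X) predict_proba(model, X)$outlier_probability
    ids <- intersect(fm$fold$test, sub$subject_id[sub$group %in% groups])
    for (sid in ids) {
      sc <- cohort_subset(cohort, sid)
      x <- cohort_matrix(sc)
      expl <- lapply(seq_len(nrow(x)), function(i) {
        explain_sample(prob_fn, x[i, ], stats_f,
                       n_perturbations = n_perturbations,
                       n_features = n_features,
                       seed = derive_seed(seed, "lime", sid, i))
      })
      out[[sid]] <- aggregate_subject_explanations(expl, top_k = top_k,
                                                   subject_id = sid)
    }
  }
  out
}
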