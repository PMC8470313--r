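# The screening experiment: subject-grouped cross-validation,
# per-fold standardization, one-class SVM with random hyperparameter
# search and Platt calibration, and a calibrated random-forest binary
# baseline.

#' Subject-grouped cross-validation plan
#'
#' Whole subjects (all their repeated measurements) are assigned to folds,
#' separately per group label so that healthy and pathology subjects both
#' appear in every fold's test set. Within each fold's non-test side, a
#' `validation_fraction` of subjects per group is held out for
#' hyperparameter selection and probability calibration; the rest are the
#' actual training subjects. No subject ever appears on both sides of a
#' split, which prevents leakage of repeated measurements.
#'
#' @param cohort a `posture_cohort` (may contain several groups).
#' @param n_folds number of folds (default 5).
#' @param validation_fraction fraction of non-test subjects (per group) held
#'   out for validation (default 0.2).
#' @param seed integer seed.
#' @return a list of class `split_plan` with `folds` (each a list of
#'   character vectors `train`, `validation`, `test`), `n_folds`,
#'   `validation_fraction`.
#' @export
make_grouped_folds <- function(cohort, n_folds = 5L, validation_fraction = 0.2,
                               seed = 1L) {
  sub <- cohort_subjects(cohort)
  by_group <- split_c(sub$subject_id, sub$group)
  small <- names(by_group)[vapply(by_group, length, integer(1)) < n_folds]
  if (length(small)) {
    stop("group(s) with fewer subjects than folds: ",
         paste(small, collapse = ", "))
  }
  with_seed(seed, {
    fold_of <- list()
    for (g in names(by_group)) {
      ids <- sample(by_group[[g]])
      fold_of[[g]] <- split(ids, rep_len(seq_len(n_folds), length(ids)))
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- unlist(lapply(fold_of, `[[`, f), use.names = FALSE)
      train <- character(0); validation <- character(0)
      for (g in names(by_group)) {
        rest <- sample(setdiff(by_group[[g]], fold_of[[g]][[f]]))
        n_val <- max(1L, round(validation_fraction * length(rest)))
        validation <- c(validation, rest[seq_len(n_val)])
        train <- c(train, rest[-seq_len(n_val)])
      }
      list(train = sort_c(train), validation = sort_c(validation),
           test = sort_c(test))
    })
    structure(list(folds = folds, n_folds = as.integer(n_folds),
                   validation_fraction = validation_fraction),
              class = "split_plan")
  })
}

#' Feature standardizer fitted on training data only
#'
#' @param x numeric training matrix (or `posture_cohort`).
#' @return a list of class `standardizer` with `means` and `sds`.
#' @export
fit_standardizer <- function(x) {
  if (inherits(x, "posture_cohort")) x <- cohort_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardizer needs at least 2 training samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant feature(s) in training data: ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "))
  }
  structure(list(means = colMeans(x), sds = sds), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std a `standardizer`.
#' @export
apply_standardizer <- function(std, x) {
  if (inherits(x, "posture_cohort")) x <- cohort_matrix(x)
  sweep(sweep(as.matrix(x), 2, std$means), 2, std$sds, `/`)
}

#' Random hyperparameter search for the one-class SVM
#'
#' Draws `n_iter` configurations (kernel uniform over linear/RBF, `nu`
#' log-uniform on `[0.01, 0.5]`, `gamma` log-uniform on `[1e-4, 1e1]`),
#' fits each on the healthy training samples and scores it by the ratio of
#' misclassified healthy subjects (predicted outliers) to all healthy
#' subjects in the validation set. When `val_subjects` is given, a subject
#' counts as misclassified if more than half of its measurements score as
#' outliers; without it, every sample is its own subject (sample-level
#' ratio). Returns the configuration minimizing the ratio; ties are broken
#' by smaller `nu`, then first-seen order. Degenerate fits (constant
#' decision function, see [ocsvm_is_degenerate()]) are excluded by
#' assigning ratio 1.
#'
#' @param train_healthy,val_healthy standardized numeric matrices.
#' @param n_iter number of random draws (default 50).
#' @param seed integer seed.
#' @param val_subjects optional subject ID per row of `val_healthy`.
#' @return list with `kernel`, `nu`, `gamma`, `val_ratio` and the full
#'   `draws` log.
#' @export
search_one_class_hyperparameters <- function(train_healthy, val_healthy,
                                             n_iter = 50L, seed = 1L,
                                             val_subjects = NULL) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  if (is.null(val_subjects)) {
    val_subjects <- as.character(seq_len(nrow(as.matrix(val_healthy))))
  }
  draws <- with_seed(seed, data.frame(
    kernel = sample(c("linear", "rbf"), n_iter, replace = TRUE),
    nu = exp(runif(n_iter, log(0.01), log(0.5))),
    gamma = exp(runif(n_iter, log(1e-4), log(1e1)))
  ))
  draws$val_ratio <- vapply(seq_len(n_iter), function(i) {
    fit <- ocsvm_fit(train_healthy, kernel = draws$kernel[i],
                     nu = draws$nu[i], gamma = draws$gamma[i])
    if (ocsvm_is_degenerate(fit)) return(1)
    outlier <- ocsvm_score(fit, val_healthy) > 0
    mean(tapply(outlier, val_subjects, mean) > 0.5)
  }, numeric(1))
  best <- order(draws$val_ratio, draws$nu, seq_len(n_iter))[1]
  list(kernel = draws$kernel[best], nu = draws$nu[best],
       gamma = draws$gamma[best], val_ratio = draws$val_ratio[best],
       draws = draws)
}

#' Train the one-class model on healthy training samples
#'
#' Thin wrapper around [ocsvm_fit()] taking a hyperparameter list as
#' returned by [search_one_class_hyperparameters()].
#'
#' @param train_healthy standardized healthy training matrix.
#' @param params list with `kernel`, `nu`, `gamma`.
#' @return an `ocsvm` fit.
#' @export
train_one_class <- function(train_healthy, params) {
  ocsvm_fit(train_healthy, kernel = params$kernel, nu = params$nu,
            gamma = params$gamma %||% 1 / ncol(as.matrix(train_healthy)))
}

#' Calibrate a decision function into an outlier-probability model
#'
#' Scores the calibration samples with the fitted decision function
#' (orientation: larger = more outlier-like) and fits a Platt sigmoid with
#' cross-validated ridge strength. Bundles standardizer, decision function
#' and sigmoid into a deployable calibrated model.
#'
#' @param fit an `ocsvm` or `rf_model` fit.
#' @param samples calibration samples: raw feature matrix or cohort if
#'   `standardizer` is given, otherwise already standardized.
#' @param labels 0/1 labels (healthy = 0, outlier = 1); both required.
#' @param cv_folds CV folds for the penalty search (default 5).
#' @param standardizer optional `standardizer` to bundle.
#' @param seed integer seed for calibration folds.
#' @return a list of class `calibrated_model`: `standardizer`, `fit`,
#'   `model_kind` (`"one_class"` or `"binary"`), `platt`.
#' @export
platt_calibrate <- function(fit, samples, labels, cv_folds = 5L,
                            standardizer = NULL, seed = 1L) {
  z <- if (is.null(standardizer)) {
    if (inherits(samples, "posture_cohort")) cohort_matrix(samples) else as.matrix(samples)
  } else {
    apply_standardizer(standardizer, samples)
  }
  kind <- if (inherits(fit, "ocsvm")) "one_class" else "binary"
  scores <- raw_score(fit, z)
  platt <- platt_fit(scores, labels, cv_folds = cv_folds, seed = seed)
  structure(list(standardizer = standardizer, fit = fit, model_kind = kind,
                 platt = platt),
            class = "calibrated_model")
}

# Oriented raw score (larger = more outlier-like) for any supported fit.
raw_score <- function(fit, z) {
  if (inherits(fit, "ocsvm")) return(ocsvm_score(fit, z))
  if (inherits(fit, "rf_model")) return(rf_score(fit, z))
  stop("unsupported model type: ", paste(class(fit), collapse = "/"))
}

#' Predict calibrated outlier probabilities
#'
#' @param model a `calibrated_model`.
#' @param samples a `posture_cohort` or raw feature matrix (standardization
#'   is applied internally when the model carries a standardizer).
#' @return data frame with `subject_id`, `measurement_id`, `group` (when
#'   available), `raw_score`, `outlier_probability`.
#' @export
predict_proba <- function(model, samples) {
  stopifnot(inherits(model, "calibrated_model"))
  if (inherits(samples, "posture_cohort")) {
    meta <- cohort_meta(samples)
    x <- cohort_matrix(samples)
  } else {
    x <- as.matrix(samples)
    meta <- data.frame(subject_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                       measurement_id = as.character(seq_len(nrow(x))),
                       group = NA_character_, stringsAsFactors = FALSE)
  }
  z <- if (is.null(model$standardizer)) x else apply_standardizer(model$standardizer, x)
  s <- raw_score(model$fit, z)
  cbind(meta, data.frame(raw_score = s,
                         outlier_probability = platt_predict(model$platt, s)))
}

#' Train and calibrate the random-forest binary baseline
#'
#' Random search over `n_estimators` in 50..500 and `max_depth` in 2..20 or
#' unlimited; each candidate forest is trained on healthy + pathology
#' training samples and scored by F1 on the validation samples (hard 0.5
#' threshold on the vote fraction). The best forest's vote fraction is then
#' Platt-calibrated on the validation set.
#'
#' @param train_healthy,train_pathology standardized training matrices.
#' @param val_samples standardized validation matrix (both groups).
#' @param val_labels 0/1 labels for `val_samples`.
#' @param n_iter random-search budget (default 50).
#' @param seed integer seed.
#' @param standardizer optional `standardizer` to bundle into the result.
#' @return a `calibrated_model` (kind `"binary"`); element
#'   `fit$params` records the chosen hyperparameters, attribute `"search"`
#'   the draw log.
#' @export
train_binary_baseline <- function(train_healthy, train_pathology, val_samples,
                                  val_labels, n_iter = 50L, seed = 1L,
                                  standardizer = NULL) {
  if (nrow(as.matrix(train_pathology)) == 0 || nrow(as.matrix(train_healthy)) == 0) {
    stop("binary baseline requires both classes in training")
  }
  x <- rbind(as.matrix(train_healthy), as.matrix(train_pathology))
  y <- c(rep(0L, nrow(as.matrix(train_healthy))),
         rep(1L, nrow(as.matrix(train_pathology))))
  draws <- with_seed(seed, data.frame(
    n_estimators = sample(50:500, n_iter, replace = TRUE),
    max_depth = sample(c(2:20, 0L), n_iter, replace = TRUE)  # 0 = unlimited
  ))
  fits <- vector("list", n_iter)
  draws$val_f1 <- vapply(seq_len(n_iter), function(i) {
    fits[[i]] <<- rf_fit(x, y, n_trees = draws$n_estimators[i],
                         max_depth = draws$max_depth[i],
                         seed = derive_seed(seed, "rf-draw", i))
    pred <- rf_score(fits[[i]], as.matrix(val_samples)) >= 0.5
    f1(confusion_matrix(truth = val_labels == 1, predicted = pred))
  }, numeric(1))
  best <- order(-draws$val_f1, seq_len(n_iter))[1]
  model <- platt_calibrate(fits[[best]], as.matrix(val_samples), val_labels,
                           standardizer = NULL, seed = derive_seed(seed, "rf-platt"))
  model$standardizer <- standardizer
  attr(model, "search") <- draws
  model
}

#' Configuration for a screening experiment
#'
#' @param n_folds grouped CV folds (default 5).
#' @param validation_fraction per-group validation share of the non-test
#'   side (default 0.2).
#' @param n_iter random hyperparameter search budget per fold (default 50).
#' @param models which paths to run: subset of `c("one_class", "binary")`.
#' @param threshold probability threshold for class predictions (default
#'   0.5).
#' @param low_conf_margin subject-level low-confidence margin (default 0.2).
#' @param seed master seed; all per-fold and per-search seeds are derived
#'   from it via [derive_seed()].
#' @return a list of class `screening_config`.
#' @export
screening_config <- function(n_folds = 5L, validation_fraction = 0.2,
                             n_iter = 50L, models = c("one_class", "binary"),
                             threshold = 0.5, low_conf_margin = 0.2, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(n_folds = as.integer(n_folds),
                 validation_fraction = validation_fraction,
                 n_iter = as.integer(n_iter), models = models,
                 threshold = threshold, low_conf_margin = low_conf_margin,
                 seed = as.integer(seed)),
            class = "screening_config")
}

# Fit the models of a single fold. Split into its own function so tests can
# verify the no-leakage property: refitting after deleting test subjects'
# samples must reproduce the fitted parameters bitwise.
fit_fold_models <- function(cohort, fold, config, fold_index) {
  is_healthy <- function(ids) {
    sub <- cohort_subjects(cohort)
    ids[ids %in% sub$subject_id[sub$group == "healthy"]]
  }
  take <- function(ids) cohort_subset(cohort, ids)

  train_h <- take(is_healthy(fold$train))
  train_p <- take(setdiff(fold$train, is_healthy(fold$train)))
  val_h <- take(is_healthy(fold$validation))
  val_p <- take(setdiff(fold$validation, is_healthy(fold$validation)))

  std <- fit_standardizer(train_h)
  z_train_h <- apply_standardizer(std, train_h)
  z_train_p <- apply_standardizer(std, train_p)
  z_val_h <- apply_standardizer(std, val_h)
  z_val_p <- apply_standardizer(std, val_p)
  z_val <- rbind(z_val_h, z_val_p)
  y_val <- c(rep(0L, nrow(z_val_h)), rep(1L, nrow(z_val_p)))

  out <- list(standardizer = std, fold = fold, fold_index = fold_index)
  if ("one_class" %in% config$models) {
    search <- search_one_class_hyperparameters(
      z_train_h, z_val_h, n_iter = config$n_iter,
      seed = derive_seed(config$seed, "ocsvm-search", fold_index),
      val_subjects = val_h$subject_id)
    fit <- train_one_class(z_train_h, search)
    model <- platt_calibrate(fit, z_val, y_val, cv_folds = 5L,
                             seed = derive_seed(config$seed, "ocsvm-platt", fold_index))
    model$standardizer <- std
    out$one_class <- model
    out$one_class_search <- search[c("kernel", "nu", "gamma", "val_ratio")]
  }
  if ("binary" %in% config$models) {
    model <- train_binary_baseline(
      z_train_h, z_train_p, z_val, y_val, n_iter = config$n_iter,
      seed = derive_seed(config$seed, "rf-search", fold_index),
      standardizer = std)
    out$binary <- model
  }
  out
}

evaluate_fold <- function(model, cohort, test_ids, fold_index, threshold) {
  test <- cohort_subset(cohort, test_ids)
  pred <- predict_proba(model, test)
  pred$fold <- fold_index
  y <- pred$group != "healthy"
  yhat <- pred$outlier_probability >= threshold
  cm <- confusion_matrix(truth = y, predicted = yhat)
  list(cm = cm, f1 = f1(cm), mcc = mcc(cm),
       bss = brier_skill_score(pred$outlier_probability, as.integer(y)),
       predictions = pred)
}

#' Run the full screening experiment
#'
#' Combines a healthy and a pathology cohort, builds a subject-grouped
#' cross-validation plan, and per fold: standardizes on the healthy
#' training samples; trains the one-class SVM on healthy training samples
#' only (hyperparameters chosen on healthy validation samples) and
#' Platt-calibrates it on the validation subjects of both groups; trains
#' the random-forest baseline on both groups' training samples (selected by
#' validation F1) and calibrates it likewise; then predicts the fold's test
#' subjects. Pathology samples never enter one-class training; they appear
#' only in calibration (validation subjects) and testing.
#'
#' @param healthy a `posture_cohort` with group `"healthy"`.
#' @param pathology a `posture_cohort` with one non-healthy group; subject
#'   IDs must be disjoint from `healthy`.
#' @param config a [screening_config()].
#' @return a list of class `screening_experiment` with `reports` (an
#'   `evaluation_report` per requested model), `fold_models`, `plan`,
#'   `config`.
#' @export
run_experiment <- function(healthy, pathology, config = screening_config()) {
  if (length(intersect(unique(healthy$subject_id),
                       unique(pathology$subject_id)))) {
    stop("healthy and pathology cohorts share subject IDs")
  }
  if (!all(healthy$group == "healthy")) stop("healthy cohort must have group 'healthy'")
  if (any(pathology$group == "healthy")) stop("pathology cohort contains group 'healthy'")
  cohort <- cohort_rbind(healthy, pathology)
  plan <- make_grouped_folds(cohort, config$n_folds,
                             config$validation_fraction,
                             seed = derive_seed(config$seed, "folds"))
  fold_models <- vector("list", config$n_folds)
  per_fold <- list(one_class = list(), binary = list())
  for (f in seq_len(config$n_folds)) {
    fm <- tryCatch(
      fit_fold_models(cohort, plan$folds[[f]], config, f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    fold_models[[f]] <- fm
    for (m in config$models) {
      per_fold[[m]][[f]] <- evaluate_fold(fm[[m]], cohort,
                                          plan$folds[[f]]$test, f,
                                          config$threshold)
    }
  }
  reports <- lapply(config$models, function(m) {
    build_report(per_fold[[m]], config$threshold, config$low_conf_margin)
  })
  names(reports) <- config$models
  structure(list(reports = reports, fold_models = fold_models, plan = plan,
                 config = config),
            class = "screening_experiment")
}

#' @export
print.screening_experiment <- function(x, ...) {
  cat("<screening_experiment> ", x$config$n_folds, " folds\n", sep = "")
  for (m in names(x$reports)) {
    r <- x$reports[[m]]
    cat(sprintf("  %-10s F1 %.2f+/-%.2f  MCC %.2f+/-%.2f  BSS %.2f+/-%.2f\n",
                m, r$mean["f1"], r$sd["f1"], r$mean["mcc"], r$sd["mcc"],
                r$mean["bss"], r$sd["bss"]))
  }
  invisible(x)
}
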