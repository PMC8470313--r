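# End-to-end study driver: runs the screening experiment for each
# pathology cohort against one healthy cohort and emits a reproducible
# report bundle (JSON metrics, subject CSVs, explanation CSVs, manifest).

#' Configuration for a full screening study
#'
#' @param healthy healthy cohort: a `posture_cohort` or a CSV path.
#' @param pathologies named list of pathology cohorts (`posture_cohort`s or
#'   CSV paths); names label the report entries.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param models,n_folds,validation_fraction,n_iter,threshold,low_conf_margin
#'   passed to [screening_config()].
#' @param explain logical: produce per-subject explanation CSVs.
#' @param n_perturbations,n_features,top_k explainer controls.
#' @param seed master seed for the whole study.
#' @return a list of class `run_config`.
#' @export
run_config <- function(healthy, pathologies, out_dir = NULL,
                       models = c("one_class", "binary"), n_folds = 5L,
                       validation_fraction = 0.2, n_iter = 50L,
                       threshold = 0.5, low_conf_margin = 0.2,
                       explain = FALSE, n_perturbations = 2000L,
                       n_features = 10L, top_k = 3L, seed = 1L) {
  if (length(pathologies) &&
      (is.null(names(pathologies)) || any(!nzchar(names(pathologies))))) {
    stop("pathologies must be a named list")
  }
  structure(list(healthy = healthy, pathologies = pathologies,
                 out_dir = out_dir, models = models, n_folds = n_folds,
                 validation_fraction = validation_fraction, n_iter = n_iter,
                 threshold = threshold, low_conf_margin = low_conf_margin,
                 explain = explain, n_perturbations = n_perturbations,
                 n_features = n_features, top_k = top_k,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_cohort_input <- function(x) {
  if (inherits(x, "posture_cohort")) return(x)
  if (is.character(x) && length(x) == 1) return(read_cohort(x))
  stop("cohort inputs must be posture_cohort objects or CSV paths")
}

report_to_list <- function(report) {
  list(per_fold = report$per_fold,
       mean = as.list(report$mean),
       sd = as.list(report$sd),
       confusion = unclass(report$confusion),
       cm_layout = "rows = predicted class, columns = true class",
       subjects = report$subjects)
}

#' Run a full screening study
#'
#' For each pathology cohort, runs [run_experiment()] against the healthy
#' cohort (per-pathology seeds derived from the master seed) and, if an
#' output directory is configured, writes per-pathology report JSON and
#' subject CSV, optional explanation CSVs, and a manifest recording the
#' configuration, derived seeds and software versions.
#'
#' @param config a [run_config()].
#' @return the report bundle (list of class `report_bundle`): per pathology
#'   a list with `experiment`, `reports`, `subjects`, and optionally
#'   `explanations`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  healthy <- load_cohort_input(config$healthy)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  bundle <- list()
  for (name in names(config$pathologies)) {
    pathology <- load_cohort_input(config$pathologies[[name]])
    seed_p <- derive_seed(config$seed, "study", name)
    scfg <- screening_config(n_folds = config$n_folds,
                             validation_fraction = config$validation_fraction,
                             n_iter = config$n_iter, models = config$models,
                             threshold = config$threshold,
                             low_conf_margin = config$low_conf_margin,
                             seed = seed_p)
    exp <- tryCatch(run_experiment(healthy, pathology, scfg),
                    error = function(e) {
                      stop("stage run_experiment[", name, "]: ",
                           conditionMessage(e), call. = FALSE)
                    })
    entry <- list(experiment = exp,
                  reports = lapply(exp$reports, report_to_list),
                  subjects = lapply(exp$reports, `[[`, "subjects"),
                  seed = seed_p)
    if (isTRUE(config$explain)) {
      cohort <- cohort_rbind(healthy, pathology)
      entry$explanations <- lapply(config$models, function(m) {
        explain_test_folds(exp, cohort, model_kind = m,
                           n_perturbations = config$n_perturbations,
                           n_features = config$n_features,
                           top_k = config$top_k,
                           seed = derive_seed(seed_p, "explain", m))
      })
      names(entry$explanations) <- config$models
    }
    if (!is.null(out_dir)) {
      jsonlite::write_json(entry$reports,
                           file.path(out_dir, paste0(name, "_report.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      for (m in names(exp$reports)) {
        utils::write.csv(exp$reports[[m]]$subjects,
                         file.path(out_dir, paste0(name, "_", m, "_subjects.csv")),
                         row.names = FALSE)
      }
      if (isTRUE(config$explain)) {
        for (m in names(entry$explanations)) {
          tabs <- lapply(entry$explanations[[m]], function(se) {
            cbind(subject_id = se$subject_id, se$table)
          })
          utils::write.csv(do.call(rbind, tabs),
                           file.path(out_dir, paste0(name, "_", m, "_explanations.csv")),
                           row.names = FALSE)
        }
      }
    }
    bundle[[name]] <- entry
  }
  if (!is.null(out_dir)) {
    manifest <- list(
      package = "posturescreen",
      package_version = as.character(utils::packageVersion("posturescreen")),
      r_version = R.version.string,
      master_seed = config$seed,
      derived_seeds = lapply(bundle, `[[`, "seed"),
      models = config$models, n_folds = config$n_folds,
      validation_fraction = config$validation_fraction,
      n_iter = config$n_iter, threshold = config$threshold,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(bundle) <- "report_bundle"
  bundle
}

#' Render a report bundle as Markdown text
#'
#' Produces a metrics table (one row per pathology and model: F1, MCC, BSS
#' as mean +/- SD across folds, plus the summed confusion matrix) and a
#' per-subject table (mean outlier probability, predicted class, top
#' explanatory features when available).
#'
#' @param bundle a `report_bundle` from [run_full_study()].
#' @return character vector of Markdown lines.
#' @export
render_report <- function(bundle) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  lines <- c("# Screening study report", "",
             "## Classification metrics (mean ± SD across folds)", "",
             "| Data | Model | F1 | MCC | BSS | CM (tn fp fn tp) |",
             "|---|---|---|---|---|---|")
  for (name in names(bundle)) {
    entry <- bundle[[name]]
    for (m in names(entry$experiment$reports)) {
      r <- entry$experiment$reports[[m]]
      cm <- r$confusion
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %d %d %d %d |",
        name, m, fmt(r$mean["f1"], r$sd["f1"]), fmt(r$mean["mcc"], r$sd["mcc"]),
        fmt(r$mean["bss"], r$sd["bss"]), cm$tn, cm$fp, cm$fn, cm$tp))
    }
  }
  lines <- c(lines, "", "## Subject-level predictions", "")
  for (name in names(bundle)) {
    entry <- bundle[[name]]
    for (m in names(entry$experiment$reports)) {
      subj <- entry$experiment$reports[[m]]$subjects
      subj <- subj[subj$group != "healthy", , drop = FALSE]
      if (nrow(subj) == 0) next
      lines <- c(lines, sprintf("### %s / %s", name, m), "",
                 "| Subject | Mean probability | Predicted | Low confidence | Top features |",
                 "|---|---|---|---|---|")
      expl <- entry$explanations[[m]]
      for (i in seq_len(nrow(subj))) {
        sid <- subj$subject_id[i]
        top <- if (!is.null(expl) && !is.null(expl[[sid]])) {
          paste(expl[[sid]]$top_features, collapse = ", ")
        } else ""
        lines <- c(lines, sprintf(
          "| %s | %.2f ± %.2f | %s | %s | %s |",
          sid, subj$mean_outlier_probability[i], subj$sd_outlier_probability[i],
          subj$predicted_class[i], ifelse(subj$low_confidence[i], "yes", "no"),
          top))
      }
      lines <- c(lines, "")
    }
  }
  lines
}
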