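# Feature schema and cohort container for rasterstereographic posture data.

#' The canonical 55-feature spinal posture schema
#'
#' Rasterstereographic (surface-topography) systems report, per measurement,
#' four pelvic orientation parameters and the orientation of 17 vertebral
#' levels (VP = vertebra prominens, T1--T12, L1--L4) in three anatomical
#' planes, all in degrees. The canonical column order is: the four pelvic
#' parameters, then for each level the triple rotation (transversal plane),
#' lateral flexion (coronal plane), flexion-extension (sagittal plane).
#' Positive values indicate a rotation/tilt to the left or ventral (toward
#' flexion); negative values to the right or dorsal (toward extension).
#'
#' @return A data frame of class `posture_schema` with 55 rows and columns
#'   `name`, `plane` (one of `pelvic`, `transversal`, `coronal`, `sagittal`)
#'   and `level` (`pelvis`, `VP`, `T1`..`T12`, `L1`..`L4`).
#' @examples
#' sch <- posture_schema()
#' nrow(sch)            # 55
#' head(sch$name, 7)
#' @export
posture_schema <- function() {
  levels17 <- c("VP", paste0("T", 1:12), paste0("L", 1:4))
  pelvic <- data.frame(
    name = c("pelvic_obliquity_deg", "pelvic_torsion_deg",
             "pelvic_inclination_deg", "pelvic_rotation_deg"),
    plane = "pelvic",
    level = "pelvis",
    stringsAsFactors = FALSE
  )
  vert <- do.call(rbind, lapply(levels17, function(lv) {
    data.frame(
      name = paste0(lv, c("_rot_deg", "_latflex_deg", "_flexext_deg")),
      plane = c("transversal", "coronal", "sagittal"),
      level = lv,
      stringsAsFactors = FALSE
    )
  }))
  out <- rbind(pelvic, vert)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 55L, !anyDuplicated(out$name))
  class(out) <- c("posture_schema", "data.frame")
  out
}

#' Export the feature schema as JSON
#'
#' @param schema a [posture_schema()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
schema_to_json <- function(schema = posture_schema(), path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(schema), dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

schema_names <- function(schema = posture_schema()) schema$name

meta_cols <- c("subject_id", "measurement_id", "group")

#' Construct / validate a posture cohort
#'
#' A cohort is a data frame with identifier columns `subject_id`,
#' `measurement_id`, `group` followed by the 55 feature columns in canonical
#' schema order. One row is one measurement; a subject's repeated
#' measurements share its `subject_id` and must share one `group` label.
#'
#' @param df a data frame with the columns described above.
#' @param schema the feature schema (defaults to [posture_schema()]).
#' @return the validated cohort, classed `posture_cohort`.
#' @export
as_posture_cohort <- function(df, schema = posture_schema()) {
  feats <- schema_names(schema)
  missing <- setdiff(c(meta_cols, feats), names(df))
  extra <- setdiff(names(df), c(meta_cols, feats))
  if (length(missing) || length(extra)) {
    stop("cohort schema error; missing columns: [",
         paste(missing, collapse = ", "), "]; unexpected columns: [",
         paste(extra, collapse = ", "), "]")
  }
  df <- df[, c(meta_cols, feats)]
  df$subject_id <- as.character(df$subject_id)
  df$measurement_id <- as.character(df$measurement_id)
  df$group <- as.character(df$group)
  for (f in feats) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in feature '", f, "' at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (any(!is.finite(v))) {
      stop("non-finite value in feature '", f, "' at row(s) ",
           paste(head(which(!is.finite(v)), 5), collapse = ", "))
    }
  }
  gr <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(gr > 1)) {
    stop("conflicting group labels within subject(s): ",
         paste(names(gr)[gr > 1], collapse = ", "))
  }
  attr(df, "schema") <- schema
  class(df) <- c("posture_cohort", "data.frame")
  df
}

#' Build a cohort from a feature matrix
#'
#' @param x numeric matrix (rows = measurements, 55 columns in schema order).
#' @param subject_id,measurement_id,group per-row identifier vectors
#'   (`group` may be a single label, recycled).
#' @param schema feature schema.
#' @return a `posture_cohort`.
#' @export
cohort_from_matrix <- function(x, subject_id, measurement_id = NULL,
                               group = "healthy", schema = posture_schema()) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(schema)) {
    stop("feature matrix has ", ncol(x), " columns; schema requires ", nrow(schema))
  }
  if (is.null(measurement_id)) {
    measurement_id <- stats::ave(seq_len(nrow(x)), subject_id, FUN = seq_along)
    measurement_id <- sprintf("m%02d", measurement_id)
  }
  df <- data.frame(subject_id = as.character(subject_id),
                   measurement_id = as.character(measurement_id),
                   group = rep_len(as.character(group), nrow(x)),
                   stringsAsFactors = FALSE)
  feat <- as.data.frame(x)
  names(feat) <- schema_names(schema)
  as_posture_cohort(cbind(df, feat), schema)
}

#' Extract the numeric feature matrix of a cohort
#' @param cohort a `posture_cohort`.
#' @return numeric matrix, rows = measurements, 55 columns.
#' @export
cohort_matrix <- function(cohort) {
  sch <- attr(cohort, "schema") %||% posture_schema()
  as.matrix(as.data.frame(cohort)[, schema_names(sch)])
}

#' Per-row metadata of a cohort
#' @param cohort a `posture_cohort`.
#' @return data frame with `subject_id`, `measurement_id`, `group`.
#' @export
cohort_meta <- function(cohort) {
  as.data.frame(cohort)[, meta_cols]
}

#' Subject table of a cohort
#' @param cohort a `posture_cohort`.
#' @return data frame with one row per subject: `subject_id`, `group`,
#'   `n_samples`.
#' @export
cohort_subjects <- function(cohort) {
  m <- cohort_meta(cohort)
  agg <- aggregate(m$measurement_id, by = list(subject_id = m$subject_id,
                                               group = m$group), FUN = length)
  names(agg)[3] <- "n_samples"
  agg[order(agg$subject_id, method = "radix"), , drop = FALSE]
}

#' Row-subset a cohort by subject IDs
#' @param cohort a `posture_cohort`.
#' @param subject_ids character vector of subject IDs to keep.
#' @return a `posture_cohort`.
#' @export
cohort_subset <- function(cohort, subject_ids) {
  keep <- cohort$subject_id %in% subject_ids
  as_posture_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
                    attr(cohort, "schema") %||% posture_schema())
}

#' Concatenate cohorts
#' @param ... `posture_cohort` objects with identical schemas.
#' @return a `posture_cohort`.
#' @export
cohort_rbind <- function(...) {
  parts <- lapply(list(...), as.data.frame)
  as_posture_cohort(do.call(rbind, parts))
}

#' @export
print.posture_cohort <- function(x, ...) {
  sub <- cohort_subjects(x)
  cat("<posture_cohort> ", nrow(x), " measurements, ", nrow(sub),
      " subjects, groups: ",
      paste(sprintf("%s (%d)", names(table(sub$group)), table(sub$group)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a posture cohort from CSV
#'
#' Expects a comma-separated, UTF-8, `.`-decimal file with header columns
#' `subject_id`, `measurement_id`, `group` followed by the 55 canonical
#' feature columns (degrees).
#'
#' @param path CSV file path.
#' @param schema feature schema.
#' @return a `posture_cohort`.
#' @export
read_cohort <- function(path, schema = posture_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  feats <- intersect(schema_names(schema), names(df))
  for (f in feats) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]) & nzchar(df[[f]]))
    if (length(bad)) {
      stop("non-numeric feature value in column '", f, "' at data row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
    df[[f]] <- v
  }
  as_posture_cohort(df, schema)
}

#' Write a posture cohort to CSV
#'
#' Rows are ordered deterministically by subject then measurement ID, and
#' numeric values are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips doubles exactly.
#'
#' @param cohort a `posture_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sch <- attr(cohort, "schema") %||% posture_schema()
  df <- as.data.frame(cohort)
  df <- df[order(df$subject_id, df$measurement_id, method = "radix"), ,
           drop = FALSE]
  for (f in schema_names(sch)) df[[f]] <- sprintf("%.17g", df[[f]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write cohort to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
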