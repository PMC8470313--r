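# Synthetic cohort generation: a surrogate healthy population and pathology
# classes of controlled silhouette separation obtained by shifting a single
# principal component of the healthy data.

#' Specification of the surrogate healthy population model
#'
#' The generator emulates a healthy cohort measured repeatedly with a
#' rasterstereographic system. Each subject has a stable individual posture
#' (between-subject variation) around a physiological population mean, and
#' each measurement adds independent within-subject noise (device and
#' postural-sway repeatability). Between-subject variation is driven by a
#' small number of latent "postural modes" whose loadings vary smoothly
#' along the cranio-caudal level ordering, so that adjacent vertebral levels
#' are correlated, as in real spinal shape data.
#'
#' @param n_subjects number of healthy subjects.
#' @param measurements_per_subject repeated measurements per subject.
#' @param population_mean 55-vector of population means in degrees. Default:
#'   zero in the transversal and coronal planes, a smooth
#'   kyphosis/lordosis-like profile in the sagittal plane, and a typical
#'   pelvic inclination.
#' @param between_subject_sd per-feature SD of stable subject offsets
#'   (degrees; scalar recycled). Default 3.
#' @param within_subject_sd per-feature SD of measurement noise (degrees;
#'   scalar recycled). Default 1.
#' @param n_latent_factors number of latent postural modes (default 8).
#' @param factor_smoothness width, in vertebral levels, of the Gaussian
#'   bumps forming factor loadings (default 4).
#' @param factor_variance_share fraction of the between-subject variance
#'   carried by the latent modes, in `(0, 1]` (default 0.8). The remainder
#'   is a full-rank idiosyncratic subject offset: individual posture never
#'   lies exactly in a low-dimensional subspace. `1` gives a purely
#'   low-rank between-subject structure.
#' @param seed integer seed; required.
#' @return a list of class `healthy_model_spec`.
#' @export
healthy_model_spec <- function(n_subjects = 25L,
                               measurements_per_subject = 36L,
                               population_mean = NULL,
                               between_subject_sd = 3,
                               within_subject_sd = 1,
                               n_latent_factors = 8L,
                               factor_smoothness = 4,
                               factor_variance_share = 0.8,
                               seed) {
  sch <- posture_schema()
  p <- nrow(sch)
  if (is.null(population_mean)) {
    population_mean <- numeric(p)
    # stylized sagittal profile: thoracic kyphosis (ventral tilt of upper
    # levels), lumbar lordosis (dorsal tilt), in the sign convention
    # positive = ventral/flexion
    lev_idx <- match(sch$level, c("VP", paste0("T", 1:12), paste0("L", 1:4)))
    sag <- sch$plane == "sagittal"
    population_mean[sag] <- 12 * sin(2 * pi * (lev_idx[sag] - 1) / 16)
    population_mean[sch$name == "pelvic_inclination_deg"] <- 15
  }
  stopifnot(length(population_mean) == p,
            all(between_subject_sd >= 0), all(within_subject_sd >= 0),
            n_latent_factors >= 1, n_latent_factors <= p,
            factor_smoothness > 0,
            factor_variance_share > 0, factor_variance_share <= 1)
  if (missing(seed)) stop("healthy_model_spec requires an explicit seed")
  structure(list(n_subjects = as.integer(n_subjects),
                 measurements_per_subject = as.integer(measurements_per_subject),
                 population_mean = population_mean,
                 between_subject_sd = rep_len(between_subject_sd, p),
                 within_subject_sd = rep_len(within_subject_sd, p),
                 n_latent_factors = as.integer(n_latent_factors),
                 factor_smoothness = factor_smoothness,
                 factor_variance_share = factor_variance_share,
                 seed = as.integer(seed)),
            class = "healthy_model_spec")
}

# Smooth low-rank loading matrix: per factor and plane, a Gaussian bump over
# the 17 cranio-caudal levels; pelvic parameters load independently. Rows
# are rescaled so the factors carry `factor_variance_share` of the
# between-subject variance per feature.
build_factor_loadings <- function(spec, schema = posture_schema()) {
  p <- nrow(schema)
  k <- spec$n_latent_factors
  lev_idx <- match(schema$level, c("VP", paste0("T", 1:12), paste0("L", 1:4)))
  L <- matrix(0, p, k)
  for (f in seq_len(k)) {
    for (pl in c("transversal", "coronal", "sagittal")) {
      rows <- which(schema$plane == pl)
      amp <- rnorm(1)
      ctr <- runif(1, 1, 17)
      L[rows, f] <- amp * exp(-(lev_idx[rows] - ctr)^2 / (2 * spec$factor_smoothness^2))
    }
    L[schema$plane == "pelvic", f] <- rnorm(4, sd = 0.5)
  }
  rn <- sqrt(rowSums(L^2))
  rn[rn < 1e-12] <- 1e-12
  L * (sqrt(spec$factor_variance_share) * spec$between_subject_sd / rn)
}

#' Generate a surrogate healthy cohort
#'
#' Sample `i` of subject `j` is
#' `population_mean + Lambda z_j + u_j + e_ij`, where `Lambda z_j` is the
#' factor-structured subject offset, `u_j` an independent per-feature subject
#' offset (factors and `u` jointly reproduce `between_subject_sd`), and
#' `e_ij` i.i.d. measurement noise with SD `within_subject_sd`.
#'
#' @param spec a [healthy_model_spec()].
#' @return a `posture_cohort` with group `"healthy"` and subject IDs
#'   `H01, H02, ...`.
#' @export
generate_healthy_cohort <- function(spec) {
  stopifnot(inherits(spec, "healthy_model_spec"))
  if (spec$n_subjects < 1) stop("cannot generate an empty cohort: n_subjects = 0")
  sch <- posture_schema()
  p <- nrow(sch)
  with_seed(spec$seed, {
    L <- build_factor_loadings(spec, sch)
    idio_sd <- sqrt(pmax(spec$between_subject_sd^2 - rowSums(L^2), 0))
    n <- spec$n_subjects
    m <- spec$measurements_per_subject
    rows <- vector("list", n)
    for (j in seq_len(n)) {
      offset <- as.numeric(L %*% rnorm(spec$n_latent_factors)) + rnorm(p) * idio_sd
      noise <- matrix(rnorm(m * p), m, p) * rep(spec$within_subject_sd, each = m)
      rows[[j]] <- sweep(noise, 2, spec$population_mean + offset, `+`)
    }
    x <- do.call(rbind, rows)
    cohort_from_matrix(
      x,
      subject_id = rep(sprintf("H%02d", seq_len(n)), each = m),
      measurement_id = rep(sprintf("m%02d", seq_len(m)), n),
      group = "healthy", schema = sch
    )
  })
}

#' Remove multivariate outlier measurements from a healthy cohort
#'
#' Fits an isolation-forest ensemble on all measurements and removes the
#' `contamination` fraction with the most anomalous scores; subjects left
#' with fewer than `min_samples` measurements are dropped entirely. Used to
#' clean the healthy pool before one-class training, because outliers in the
#' healthy group directly shape the learned decision boundary.
#'
#' @param cohort an all-healthy `posture_cohort`.
#' @param contamination fraction of measurements to remove in `[0, 0.5)`.
#'   The default 150/900 is the realized removal fraction of the reference
#'   cleaning run this stage emulates.
#' @param min_samples minimum measurements a subject must retain (default 10).
#' @param n_trees isolation-forest size (default 100).
#' @param sample_size per-tree subsample size (default 256, capped at n).
#' @param seed integer seed.
#' @return the cleaned `posture_cohort`; attribute `"removal_log"` is a list
#'   with the removed row metadata and fully dropped subject IDs.
#' @export
remove_healthy_outliers <- function(cohort, contamination = 150 / 900,
                                    min_samples = 10L, n_trees = 100L,
                                    sample_size = 256L, seed = 1L) {
  stopifnot(contamination >= 0, contamination < 0.5)
  if (length(unique(cohort$group)) > 1) {
    stop("remove_healthy_outliers expects a single-group (healthy) cohort")
  }
  n <- nrow(cohort)
  n_remove <- round(contamination * n)
  if (n_remove == 0) {
    attr(cohort, "removal_log") <- list(removed = cohort_meta(cohort)[0, ],
                                        dropped_subjects = character(0))
    return(cohort)
  }
  x <- cohort_matrix(cohort)
  scores <- iforest_scores_cpp(x, as.integer(n_trees),
                               as.integer(min(sample_size, n)),
                               as.integer(seed))
  drop_rows <- order(scores, decreasing = TRUE)[seq_len(n_remove)]
  keep <- setdiff(seq_len(n), drop_rows)
  kept <- as.data.frame(cohort)[keep, , drop = FALSE]
  cnt <- table(factor(kept$subject_id, levels = unique(cohort$subject_id)))
  dropped_subjects <- names(cnt)[cnt < min_samples]
  kept <- kept[!(kept$subject_id %in% dropped_subjects), , drop = FALSE]
  if (nrow(kept) == 0) stop("contamination removed every subject")
  out <- as_posture_cohort(kept, attr(cohort, "schema") %||% posture_schema())
  attr(out, "removal_log") <- list(
    removed = cohort_meta(cohort)[drop_rows, ],
    dropped_subjects = dropped_subjects,
    scores = scores
  )
  out
}

#' Standardized principal component analysis of a posture cohort
#'
#' Features are centered and scaled to unit variance, then decomposed into
#' orthonormal principal components sorted by decreasing explained variance.
#' The basis supports forward projection and exact back-transformation (when
#' the basis has full rank) and anchors the synthetic pathology generator.
#'
#' @param cohort a `posture_cohort` or numeric feature matrix.
#' @return a list of class `posture_pca`: `feature_means`, `feature_sds`,
#'   `components` (p x k orthonormal loadings, columns = components),
#'   `explained_variance` (per-component variances).
#' @export
fit_posture_pca <- function(cohort) {
  x <- if (inherits(cohort, "posture_cohort")) cohort_matrix(cohort) else as.matrix(cohort)
  if (nrow(x) < 2) stop("PCA requires at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant feature(s): ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  structure(list(feature_means = pc$center,
                 feature_sds = pc$scale,
                 components = pc$rotation,
                 explained_variance = pc$sdev^2),
            class = "posture_pca")
}

#' Project samples into (standardized) PC-score space
#' @param basis a `posture_pca`.
#' @param x numeric matrix or `posture_cohort`.
#' @return matrix of PC scores (n x k).
#' @export
pca_transform <- function(basis, x) {
  if (inherits(x, "posture_cohort")) x <- cohort_matrix(x)
  z <- sweep(sweep(as.matrix(x), 2, basis$feature_means), 2, basis$feature_sds, `/`)
  z %*% basis$components
}

#' Map PC scores back to the original feature space
#' @param basis a `posture_pca`.
#' @param scores matrix of PC scores (n x k).
#' @return numeric matrix in original units (degrees).
#' @export
pca_inverse_transform <- function(basis, scores) {
  z <- as.matrix(scores) %*% t(basis$components)
  sweep(sweep(z, 2, basis$feature_sds, `*`), 2, basis$feature_means, `+`)
}

#' Mean silhouette coefficient between two sample sets
#'
#' Treats the two sets as a two-cluster labeling and returns the mean
#' silhouette value `(b - a) / max(a, b)` over all points, with Euclidean
#' distances in the supplied feature space. Used to measure the separation
#' of a synthetic pathology class from the healthy reference.
#'
#' @param samples_a,samples_b numeric matrices with matching columns, each
#'   with at least 2 rows.
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_between <- function(samples_a, samples_b) {
  a <- as.matrix(samples_a); b <- as.matrix(samples_b)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("each sample set needs at least 2 points")
  x <- rbind(a, b)
  d <- as.matrix(dist(x))
  ia <- seq_len(na); ib <- na + seq_len(nb)
  s <- numeric(na + nb)
  for (i in seq_len(na + nb)) {
    own <- if (i <= na) setdiff(ia, i) else setdiff(ib, i)
    oth <- if (i <= na) ib else ia
    ai <- mean(d[i, own]); bi <- mean(d[i, oth])
    s[i] <- (bi - ai) / max(ai, bi)
  }
  mean(s)
}

#' Specification of one synthetic pathology class
#'
#' @param label class label, conventionally `"S1"`..`"S4"`.
#' @param pc_index 1-based index of the principal component to shift.
#' @param target_silhouette desired silhouette separation from the healthy
#'   reference, in `(-1, 1)`. Reference targets: S1 0.49 (PC 1), S2 0.41
#'   (PC 2), S3 0.33 (PC 3), S4 0.16 (PC 4).
#' @param n_subjects subjects in the class (default 24).
#' @param samples_per_subject measurements per subject (default 10).
#' @param noise_sd SD of the Gaussian on the shifted component, in
#'   standardized PC-score units (fixed default 1).
#' @param seed integer seed.
#' @return a list of class `synthetic_class_spec`.
#' @export
synthetic_class_spec <- function(label, pc_index, target_silhouette,
                                 n_subjects = 24L, samples_per_subject = 10L,
                                 noise_sd = 1, seed) {
  stopifnot(pc_index >= 1, target_silhouette > -1, target_silhouette < 1,
            n_subjects >= 1, samples_per_subject >= 1, noise_sd >= 0)
  if (missing(seed)) stop("synthetic_class_spec requires an explicit seed")
  structure(list(label = as.character(label), pc_index = as.integer(pc_index),
                 target_silhouette = target_silhouette,
                 n_subjects = as.integer(n_subjects),
                 samples_per_subject = as.integer(samples_per_subject),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_class_spec")
}

#' Generate a synthetic pathology class at a target silhouette separation
#'
#' Each synthetic sample reuses a full PC-score row resampled from the
#' healthy reference pool (so off-mode posture variation stays
#' healthy-like), except on `pc_index`, where the standardized score is
#' drawn from `Normal(center, noise_sd)`. The center is found by monotone
#' bisection so that the two-cluster silhouette between the class and the
#' healthy reference (computed in the standardized feature space) hits
#' `target_silhouette` within `tol`. Samples are mapped back to degrees via
#' the inverse standardized-PCA transform and assigned to
#' `n_subjects` subjects with `samples_per_subject` samples each.
#'
#' @param basis a `posture_pca` fitted on `healthy_reference`.
#' @param spec a [synthetic_class_spec()].
#' @param healthy_reference the healthy `posture_cohort` (or feature matrix)
#'   the basis was fitted on.
#' @param tol silhouette tolerance (default 0.02; the bisection itself aims
#'   at 0.005).
#' @param max_iter bisection iteration cap (default 60).
#' @param center_range search interval for the center, in PC-SD units
#'   (default `c(0, 20)`).
#' @return a `posture_cohort` with group `spec$label`; attributes
#'   `"achieved_silhouette"` and `"center"` record the calibration.
#' @export
generate_pathology_class <- function(basis, spec, healthy_reference,
                                     tol = 0.02, max_iter = 60L,
                                     center_range = c(0, 20)) {
  stopifnot(inherits(basis, "posture_pca"),
            inherits(spec, "synthetic_class_spec"))
  if (spec$pc_index > ncol(basis$components)) {
    stop("pc_index ", spec$pc_index, " exceeds the ", ncol(basis$components),
         " fitted components")
  }
  href <- if (inherits(healthy_reference, "posture_cohort")) {
    cohort_matrix(healthy_reference)
  } else as.matrix(healthy_reference)
  if (nrow(href) == 0) stop("healthy_reference is empty")
  zh <- sweep(sweep(href, 2, basis$feature_means), 2, basis$feature_sds, `/`)
  scores_h <- zh %*% basis$components
  sd_pc <- sqrt(basis$explained_variance[spec$pc_index])
  n_new <- spec$n_subjects * spec$samples_per_subject

  # one frozen stochastic realization per class: the bisection then sees a
  # deterministic, monotone map from center to silhouette
  draws <- with_seed(spec$seed, list(
    rows = sample.int(nrow(scores_h), n_new, replace = TRUE),
    eps = rnorm(n_new)
  ))
  s0 <- scores_h[draws$rows, , drop = FALSE]

  class_z <- function(center) {
    s <- s0
    s[, spec$pc_index] <- (center + draws$eps * spec$noise_sd) * sd_pc
    s %*% t(basis$components)
  }
  sil_at <- function(center) silhouette_between(class_z(center), zh)

  lo <- center_range[1]; hi <- center_range[2]
  s_lo <- sil_at(lo); s_hi <- sil_at(hi)
  if (spec$target_silhouette < s_lo - tol || spec$target_silhouette > s_hi + tol) {
    stop("target silhouette ", spec$target_silhouette,
         " not attainable in center range [", lo, ", ", hi, "]: achievable [",
         round(s_lo, 3), ", ", round(s_hi, 3), "]")
  }
  center <- (lo + hi) / 2; achieved <- sil_at(center)
  iter <- 0L
  while (abs(achieved - spec$target_silhouette) > 0.005 && iter < max_iter) {
    if (achieved > spec$target_silhouette) hi <- center else lo <- center
    center <- (lo + hi) / 2
    achieved <- sil_at(center)
    iter <- iter + 1L
  }
  if (abs(achieved - spec$target_silhouette) > tol) {
    stop("silhouette bisection did not converge: best achieved ",
         round(achieved, 4), " for target ", spec$target_silhouette)
  }
  x <- sweep(sweep(class_z(center), 2, basis$feature_sds, `*`),
             2, basis$feature_means, `+`)
  colnames(x) <- names(basis$feature_means)
  out <- cohort_from_matrix(
    x,
    subject_id = rep(sprintf("%s_%02d", spec$label, seq_len(spec$n_subjects)),
                     each = spec$samples_per_subject),
    measurement_id = rep(sprintf("m%02d", seq_len(spec$samples_per_subject)),
                         spec$n_subjects),
    group = spec$label
  )
  attr(out, "achieved_silhouette") <- achieved
  attr(out, "center") <- center
  out
}

#' Draw a fixed number of samples per subject without replacement
#'
#' Real and synthetic subjects enter the modeling stage with the same number
#' of measurements (default 10 in the screening pipeline), drawn uniformly
#' without replacement from each subject's available measurements.
#'
#' @param cohort a `posture_cohort`.
#' @param n samples to retain per subject.
#' @param seed integer seed.
#' @return a `posture_cohort` with exactly `n` samples per subject.
#' @export
draw_subject_samples <- function(cohort, n = 10L, seed = 1L) {
  cnt <- table(cohort$subject_id)
  short <- names(cnt)[cnt < n]
  if (length(short)) {
    stop("subject(s) with fewer than ", n, " samples: ",
         paste(short, collapse = ", "))
  }
  df <- as.data.frame(cohort)
  keep <- with_seed(seed, {
    unlist(lapply(split_c(seq_len(nrow(df)), df$subject_id), function(ix) {
      if (length(ix) == n) ix else sort(sample(ix, n))
    }), use.names = FALSE)
  })
  as_posture_cohort(df[sort(keep), , drop = FALSE],
                    attr(cohort, "schema") %||% posture_schema())
}
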