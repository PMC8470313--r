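# Shared fixtures, all generated in code.

feat_names <- posture_schema()$name

# small healthy cohort (defaults: 12 subjects x 6 measurements)
make_healthy <- function(n_subjects = 12, m = 6, seed = 101, ...) {
  generate_healthy_cohort(healthy_model_spec(
    n_subjects = n_subjects, measurements_per_subject = m, seed = seed, ...))
}

# hand-built tiny cohort: 2 subjects x 3 measurements, deterministic values
make_tiny_cohort <- function() {
  x <- matrix(seq_len(6 * 55) / 7, nrow = 6)
  cohort_from_matrix(x,
                     subject_id = rep(c("A", "B"), each = 3),
                     measurement_id = rep(c("m1", "m2", "m3"), 2),
                     group = rep(c("healthy", "S1"), each = 3))
}

# the reference protocol: generate, clean, draw 10 per subject
make_reference_healthy <- function(seed = 42) {
  h0 <- generate_healthy_cohort(healthy_model_spec(seed = seed))
  hc <- remove_healthy_outliers(h0, seed = seed + 1)
  draw_subject_samples(hc, 10, seed = seed + 2)
}

# independent brute-force silhouette oracle (two clusters, Euclidean)
silhouette_oracle <- function(a, b) {
  pts <- rbind(a, b)
  lab <- c(rep(1, nrow(a)), rep(2, nrow(b)))
  n <- nrow(pts)
  s <- numeric(n)
  for (i in seq_len(n)) {
    da <- db <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (lab[j] == lab[i]) da <- c(da, dij) else db <- c(db, dij)
    }
    s[i] <- (mean(db) - mean(da)) / max(mean(da), mean(db))
  }
  mean(s)
}
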