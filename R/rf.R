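# R-facing wrapper around the compiled random forest.

#' Fit a binary random-forest classifier
#'
#' CART trees with Gini splits, grown on bootstrap samples with
#' `mtry = floor(sqrt(p))` features considered per split. Used as the
#' pathology-dependent binary baseline of the screening pipeline.
#'
#' @param x numeric training matrix.
#' @param y 0/1 integer labels (1 = outlier/pathology).
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth; `0` means unlimited.
#' @param mtry features considered per split (default `floor(sqrt(p))`).
#' @param seed integer seed (deterministic given seed).
#' @return an object of class `rf_model`.
#' @export
rf_fit <- function(x, y, n_trees = 100L, max_depth = 0L, mtry = NULL,
                   seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)), n_trees >= 1)
  if (length(unique(y)) < 2) stop("random forest requires both classes in training")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- rf_fit_cpp(x, y, as.integer(n_trees), as.integer(max_depth),
                       as.integer(mtry), as.integer(seed))
  structure(list(forest = forest,
                 params = list(n_estimators = as.integer(n_trees),
                               max_depth = as.integer(max_depth),
                               mtry = as.integer(mtry), seed = as.integer(seed))),
            class = "rf_model")
}

#' Random-forest outlier score
#'
#' The raw score is the fraction of trees voting the outlier class, in
#' `[0, 1]`; larger = more outlier-like (same orientation as
#' [ocsvm_score()]).
#'
#' @param object an `rf_model`.
#' @param newdata numeric matrix.
#' @return numeric vector in `[0, 1]`.
#' @export
rf_score <- function(object, newdata) {
  as.numeric(rf_vote_cpp(object$forest, as.matrix(newdata)))
}
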