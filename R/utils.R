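# Internal helpers: reproducible seeding and RNG hygiene.

#' Derive a child seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline (fold assignment, hyperparameter
#' draws, model fitting, perturbation sampling) receives its own seed derived
#' deterministically from a single master seed plus a stage label, so that a
#' full study is reproducible from one integer while stages remain
#' statistically independent.
#'
#' @param seed master seed (integer).
#' @param ... stage labels (characters or integers), e.g. `"fold", 3`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(labels)
  h <- sum(codes * seq_along(codes)) %% 104729
  # 48271 is a classic Lehmer multiplier; all arithmetic stays < 2^53 so it
  # is exact in doubles, and the result fits in a 32-bit integer.
  as.integer((as.numeric(seed) %% 2147483399 * 48271 + h * 7919) %% 2147483399)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent ordering helpers: all subject/group orderings that feed
# RNG streams or reported tables use radix (C-locale) ordering so results do
# not depend on LC_COLLATE.
sort_c <- function(x) sort(x, method = "radix")

factor_c <- function(x) factor(x, levels = sort(unique(x), method = "radix"))

split_c <- function(x, f) split(x, factor_c(f))
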