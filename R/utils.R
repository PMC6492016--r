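#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb a
# user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed for a named sub-stream of a root seed.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  lo_ok <- if (open) x > 0 else x >= 0
  hi_ok <- if (open) x < 1 else x <= 1
  if (any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok)) {
    stop_input("`%s` must lie in %s0, 1%s", name,
               if (open) "(" else "[", if (open) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop_input("`%s` must be a single positive integer", name)
  }
  invisible(as.integer(x))
}

# Stratified assignment of n labelled samples to `folds` folds (or to a
# test fraction); returns integer fold ids / logical test mask.
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

stratified_test_mask <- function(labels, test_fraction) {
  test <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    test[sample(idx, n_test)] <- TRUE
  }
  test
}
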