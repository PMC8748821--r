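#' Derive a reproducible child seed from a master seed
#'
#' Randomized stages (bootstraps, permutations, per-subject simulation) each
#' draw their own seed from the stage's master seed and a counter, so any
#' single iteration can be reproduced in isolation without replaying the
#' whole run.
#'
#' @param master Integer master seed.
#' @param counter Non-negative integer stage/iteration counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m)
  # two rounds of a multiplicative-congruential mix; constants from MINSTD
  s <- (s * 48271 + counter + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg) stop(msg, call. = FALSE)

# checks a numeric matrix is finite, with informative message
check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    abort_input(sprintf("%s contains non-finite values", what))
  }
  invisible(x)
}
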