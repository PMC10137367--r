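# Internal helpers shared across the package.

VIEWS <- c("AP", "LAT")
VERTEBRAE <- c("L1", "L2", "L3", "L4", "L5")
POINT_IDS <- c("p1", "p2", "p3", "p4")
LINES <- c("UVEL", "LVEL")
CONSENSUS_ID <- "CONSENSUS"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never perturb (or depend on) the session's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Derive a child seed from a user seed so that independent stages of one run
# (anatomy, rater noise, bootstraps per row) use decorrelated streams while
# remaining fully determined by the single user-facing seed. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

# paste a composite key for error messages
key_string <- function(df, cols) {
  apply(df[, cols, drop = FALSE], 1L, paste, collapse = "/")
}
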