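# Small shared helpers.

# save / restore the global RNG state so package internals that seed the
# generator never disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# evaluate expr with a locally seeded RNG
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Dice coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; symmetric in its arguments; by
#' convention 1 when both masks are empty.
#'
#' @param a,b Logical matrices/arrays of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
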