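# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not disturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed, staying within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7 * k) %% 2147483647L)
}

# Competition ranks with average ties, rank 1 = largest value; NAs stay NA.
rank_desc <- function(x) rank(-x, ties.method = "average", na.last = "keep")

assert_square <- function(W, arg = "W") {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
}
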