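#' Derive reproducible sub-seeds from a master seed
#'
#' One master seed fans out to per-session, per-match and per-search
#' sub-seeds so that any single match can be replayed in isolation from its
#' logged seeds. The split is computed in an isolated RNG scope: the
#' caller's `.Random.seed` is saved and restored, so package simulations
#' never perturb (nor depend on) the global R random-number stream.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to draw.
#' @param salt Optional integer mixed into the seed, so independent
#'   components (boards, matches, searches) get disjoint streams.
#' @return An integer vector of `n` sub-seeds, each in `[1, 2^31 - 2]`.
#' @examples
#' split_seed(42, 3)
#' identical(split_seed(42, 3), split_seed(42, 3))
#' @export
split_seed <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed((as.integer(seed) + 977L * as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, as.integer(n), replace = FALSE)
}
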