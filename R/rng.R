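# Counter-based uniform streams. Every random quantity in the simulation is a
# deterministic function of (seed, individual id, purpose, k1, k2), so the
# same person sees identical draws under every strategy and scenario (common
# random numbers) and the R reference path reproduces the C++ engine exactly.

# purpose codes; the C++ engine uses the same numbering
.P <- list(
  frailty = 1, ocd = 2, n_adenomas = 3, onset = 4, segment = 5,
  growth = 6, transition = 7, sojourn = 8, stage = 9,
  surv_cure = 10, surv_time = 11,
  stool = 12, detect = 13, reach = 14, fp = 15, compl = 16,
  sex = 17
)

#' Hashed uniform draws
#'
#' Deterministic uniform(0,1) variates from a splitmix64 counter-based
#' generator keyed by `(seed, id, purpose, k1, k2)`. This is the package's
#' single source of randomness: each individual owns a named substream per
#' purpose, which is what makes strategy and scenario comparisons paired
#' (common random numbers). Arguments are recycled to the longest length.
#'
#' @param seed integer master seed.
#' @param id individual identifier(s), non-negative integers.
#' @param purpose integer purpose code (substream name).
#' @param k1,k2 integer counters within the substream (e.g. lesion index,
#'   exam age).
#' @return numeric vector of uniforms strictly inside (0, 1).
#' @examples
#' hash_u01(1, 1:5, 3)
#' @export
hash_u01 <- function(seed, id, purpose, k1 = 0, k2 = 0) {
  cpp_hash_u01(as.double(seed), as.double(id), as.double(purpose),
               as.double(k1), as.double(k2))
}
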