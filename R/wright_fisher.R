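# Core neutral Wright-Fisher machinery shared by the synthetic-data
# generator and the simulation-based likelihood for 2Ne.

#' Simulate per-mutation Wright-Fisher trajectories
#'
#' Each of `n` mutations starts at `init` copies among `two_ne` haploid
#' genomes and is resampled binomially each generation. Absorbing states
#' (0 and `two_ne` copies) are permanent.
#'
#' @param two_ne Haploid population size (>= 2).
#' @param n Number of independent trajectories.
#' @param t Number of generations to simulate.
#' @param init Initial copy number (default 1, a new mutation).
#' @return An integer matrix of dim `n x (t + 1)`; column `g + 1` holds the
#'   copy number after `g` generations of drift.
#' @examples
#' tr <- wf_trajectories(23, n = 100, t = 60)
#' @export
wf_trajectories <- function(two_ne, n, t, init = 1L) {
  if (two_ne < 2) stop("two_ne must be >= 2")
  out <- matrix(0L, nrow = n, ncol = t + 1)
  out[, 1] <- as.integer(init)
  cur <- out[, 1]
  for (g in seq_len(t)) {
    seg <- cur > 0L & cur < two_ne
    if (any(seg))
      cur[seg] <- stats::rbinom(sum(seg), two_ne, cur[seg] / two_ne)
    out[, g + 1] <- cur
  }
  out
}

# One Wright-Fisher generation applied to aggregated state counts.
# `counts` is a vector of length two_ne + 1: counts[j + 1] mutations
# currently at j copies. Returns the post-resampling counts. Distributionally
# identical to resampling every mutation individually, because unlinked
# trajectories are exchangeable given their current copy number.
wf_step_counts <- function(counts, two_ne, probs) {
  new <- numeric(two_ne + 1)
  new[1] <- counts[1]
  new[two_ne + 1] <- counts[two_ne + 1]
  for (j in seq_len(two_ne - 1)) {
    m <- counts[j + 1]
    if (m > 0) new <- new + stats::rmultinom(1, m, probs[[j + 1]])[, 1]
  }
  new
}

# Binomial transition kernels for each copy-number state.
wf_kernels <- function(two_ne) {
  lapply(0:two_ne, function(j) stats::dbinom(0:two_ne, two_ne, j / two_ne))
}

#' Kimura fixation probability of a new semidominant mutation
#'
#' Closed form `u = (1 - exp(-2 s)) / (1 - exp(-4 s Ne))` for the fixation
#' probability of a single new mutation with heterozygous selection
#' coefficient `s` in a population of effective size `Ne` diploids
#' (`2 Ne` haploid genomes). The neutral limit `s -> 0` is `1 / (2 Ne)`.
#'
#' @param s Selection coefficient(s); may be negative, zero or positive.
#' @param ne Effective population size (diploid; `ne > 0`).
#' @return Fixation probability, vectorized over `s`.
#' @examples
#' fixation_probability(0.01, 11.5)   # ~0.054
#' fixation_probability(0, 11.5)      # 1/23
#' @export
fixation_probability <- function(s, ne) {
  if (any(ne <= 0)) stop("ne must be positive")
  num <- -expm1(-2 * s)
  den <- -expm1(-4 * s * ne)
  out <- ifelse(abs(4 * s * ne) < 1e-8, 1 / (2 * ne), num / den)
  out
}
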