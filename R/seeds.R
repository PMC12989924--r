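#' Derive a reproducible sub-seed
#'
#' Deterministically maps a root seed plus one or more integer stream labels to
#' a new seed in \code{[1, 2^31 - 2]}. Every stochastic function in the package
#' takes an explicit seed; loops over simulation replicates, permutations,
#' cross-validation folds or tree nodes derive their own sub-streams with this
#' helper, so results are reproducible and independent of evaluation order.
#'
#' @param seed integer root seed.
#' @param ... integer stream labels (e.g. replicate index, node path).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.double(seed %% m)
  for (k in c(...)) {
    # Lehmer-style mix; 69069 * 2^31 < 2^53 so the double arithmetic is exact
    s <- (s * 69069 + as.double(k %% m) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  force(seed) # the seed expression may read the caller's RNG stream
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Monte-Carlo standard error of a rejection-rate estimate
#'
#' For an estimated rejection probability \code{p} from \code{nsim} independent
#' simulation rounds, the binomial standard error is
#' \code{sqrt(p * (1 - p) / nsim)}; its upper bound over p is
#' \code{0.5 / sqrt(nsim)}.
#'
#' @param p estimated rejection rate.
#' @param nsim number of simulation rounds.
#' @return standard error estimate.
#' @export
mc_se <- function(p, nsim) sqrt(p * (1 - p) / nsim)

#' @rdname mc_se
#' @export
mc_se_bound <- function(nsim) 0.5 / sqrt(nsim)

#' Number of distinct group assignments
#'
#' The permutation group of joint (time, status) relabelings has n! elements,
#' but the two-sample statistic only depends on which subjects land in group 1,
#' leaving \code{choose(n1 + n2, n1)} distinct assignments.
#'
#' @param n1,n2 group sizes.
#' @param log if \code{TRUE} return the natural log of the count.
#' @return count of distinct assignments (possibly \code{Inf} as a double).
#' @export
n_assignments <- function(n1, n2, log = FALSE) {
  lc <- lchoose(n1 + n2, n1)
  if (log) lc else exp(lc)
}
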