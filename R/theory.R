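#' Closed-form expectations for non-recombining neutral populations
#'
#' Reference values for stationary observables of a size-`N` Wright-Fisher
#' population without recombination, used as oracles in tests and available to
#' users.  The central parameter is the viability-adjusted scaled mutation
#' rate \eqn{\theta^* = 2 p N U}; on a fully viable landscape (`p = 1`) it
#' reduces to the familiar \eqn{\theta = 2 N U}, and all functions below take
#' \eqn{\theta^*} so that a single code path covers both cases.
#'
#' @param N Population size.
#' @param U Genome-wide mutation rate.
#' @param p Fraction of viable genotypes.
#' @param theta_star Viability-adjusted scaled mutation rate `2 * p * N * U`.
#' @name theory
NULL

#' @describeIn theory Scaled mutation rates: returns a list with `theta = 2NU`
#'   and `theta_star = 2pNU`.
#' @export
theta_params <- function(N, U, p = 1) {
  stopifnot(N >= 1, U >= 0, p >= 0, p <= 1)
  list(N = N, U = U, p = p, theta = 2 * N * U, theta_star = 2 * p * N * U)
}

#' @describeIn theory Discovery rate of novel viable genotypes without
#'   recombination: `p * N * (1 - exp(-U))`.  Each individual acquiring at
#'   least one mutation displays a brand-new genotype, viable with
#'   probability `p`.
#' @export
discovery_rate_r0 <- function(N, U, p = 1) {
  stopifnot(N >= 1, U >= 0, p >= 0, p <= 1)
  p * N * (1 - exp(-U))
}

#' @describeIn theory Fixation rate of mutations without recombination:
#'   `p * U / (exp(-U) + p * (1 - exp(-U)))`.  Of the `p N U` viable novel
#'   mutations arising per generation, only those in the individual that
#'   becomes the common ancestor of the whole population fix; that
#'   probability is the reciprocal of the mean number of viable individuals
#'   per generation, `N exp(-U) + N p (1 - exp(-U))`.  For `U << 1` the rate
#'   approaches the classical neutral substitution rate `p * U`.
#' @export
fixation_rate_r0 <- function(U, p = 1) {
  stopifnot(U >= 0, p >= 0, p <= 1)
  if (U == 0) return(0)
  p * U / (exp(-U) + p * (1 - exp(-U)))
}

#' @describeIn theory Stationary mean number of distinct genotypes without
#'   recombination (the Ewens-sampling expectation for the number of distinct
#'   alleles): `sum_{i=0}^{N-1} theta_star / (theta_star + i)`.
#' @export
expected_distinct_genotypes_r0 <- function(N, theta_star) {
  stopifnot(N >= 1, theta_star >= 0)
  i <- 0:(N - 1)
  if (theta_star == 0) return(1)
  sum(theta_star / (theta_star + i))
}

#' @describeIn theory Stationary mean number of segregating mutations without
#'   recombination (the Watterson expectation): `theta_star * H_{N-1}` with
#'   the harmonic number `H_{N-1} = sum_{i=1}^{N-1} 1/i`, from the expected
#'   total genealogical tree length `2N H_{N-1}`.
#' @export
expected_segregating_r0 <- function(N, theta_star) {
  if (N < 2) stop("segregating mutations require N >= 2")
  stopifnot(theta_star >= 0)
  theta_star * sum(1 / seq_len(N - 1))
}

#' @describeIn theory Stationary mean pairwise Hamming distance without
#'   recombination: `theta_star` (two random lineages coalesce after `N`
#'   generations on average, giving tree length `2N`).
#' @export
expected_pairwise_distance_r0 <- function(theta_star) {
  stopifnot(theta_star >= 0)
  theta_star
}

#' Hypoexponential density of the distance to the fixed-background ancestor
#'
#' Without recombination, an individual's Hamming distance `d` to the
#' ancestral genotype carrying only fixed mutations inherits the law of the
#' time to the most recent common ancestor of the population, a sum of
#' independent exponentials with rates `choose(i, 2)`, `i = N, ..., 2`,
#' rescaled to mutation-count units:
#' \deqn{f(d) = \frac{2}{\theta^*} \sum_{i=2}^{N} \binom{i}{2}
#'   e^{-\binom{i}{2} 2d/\theta^*}
#'   \prod_{j \ne i} \frac{\binom{j}{2}}{\binom{j}{2}-\binom{i}{2}}.}
#' The exact mean is `theta_star * (1 - 1/N)` (approaching `theta_star` for
#' large `N`).  The alternating product is evaluated in log space with sign
#' tracking; beyond `N = 100` catastrophic cancellation can no longer be
#' controlled in double precision and the function refuses to evaluate.
#'
#' @param d Distance (vectorized, `>= 0`).
#' @param N Population size (`2 <= N <= 100`).
#' @param theta_star Scaled mutation rate `2pNU` (`> 0`).
#' @return Density values at `d` (nonnegative up to numerical tolerance).
#' @export
hypoexponential_mrca_density <- function(d, N, theta_star) {
  stopifnot(all(d >= 0), theta_star > 0)
  if (N < 2) stop("the density requires N >= 2")
  if (N > 100) {
    stop("N > 100 exceeds the numerically stable range of the ",
         "log-space evaluation; use N <= 100")
  }
  c2 <- choose(2:N, 2)
  logc <- log(c2)
  # per-stage log|coefficient| and sign of prod_{j != i} c_j / (c_j - c_i)
  lcoef <- numeric(length(c2))
  scoef <- numeric(length(c2))
  for (k in seq_along(c2)) {
    diff <- c2[-k] - c2[k]
    lcoef[k] <- sum(logc[-k]) - sum(log(abs(diff)))
    scoef[k] <- prod(sign(diff))
  }
  vapply(d, function(dd) {
    terms <- scoef * exp(lcoef + logc - c2 * 2 * dd / theta_star)
    max(2 / theta_star * sum(terms), 0)
  }, numeric(1))
}

#' @describeIn theory Expected number of mutation events until full discovery
#'   implied by the discovery time: `t_fdis * N * L * mu` (valid while double
#'   mutations are rare, `L * mu << 1`).
#' @param t_fdis Time to full discovery in generations.
#' @param L Number of loci.
#' @param mu Per-site mutation probability.
#' @export
mutation_events_relation <- function(t_fdis, N, L, mu) {
  stopifnot(t_fdis >= 0, N >= 0, L >= 0, mu >= 0)
  t_fdis * N * L * mu
}

#' @describeIn theory Stationary mean pairwise Hamming distance in the
#'   finite-sites model on a fully viable landscape (`p = 1`) under the
#'   concurrent scheme: `2(1-mu) mu L N / (4(1-mu) mu (N-1) + 1)`,
#'   independent of the recombination rate.
#' @export
expected_pairwise_distance_fsm_p1 <- function(N, L, mu) {
  if (N < 2) stop("pairwise distance requires N >= 2")
  stopifnot(mu >= 0, mu <= 1, L >= 1)
  2 * (1 - mu) * mu * L * N / (4 * (1 - mu) * mu * (N - 1) + 1)
}
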