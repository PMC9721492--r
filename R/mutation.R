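#' Point mutation in the finite-sites model
#'
#' Each of the `L` loci flips to the opposite allele independently with
#' probability `mu`.
#'
#' @param g A [finite_genotype()].
#' @param mu Per-locus mutation probability in `[0, 1]`.
#' @return A list with elements `genotype` (the possibly mutated genotype) and
#'   `mutated` (`TRUE` iff at least one locus flipped; an individual with one
#'   or more flips counts as a single mutation event).
#' @export
mutate_finite <- function(g, mu) {
  stopifnot(inherits(g, "finite_genotype"), mu >= 0, mu <= 1)
  L <- attr(g, "L")
  nflip <- stats::rbinom(1L, L, mu)
  if (nflip == 0L) return(list(genotype = g, mutated = FALSE))
  loci <- sample.int(L, nflip)
  mask <- sum(bitwShiftL(1L, loci - 1L))
  list(genotype = finite_genotype(bitwXor(unclass(g)[1L], mask), L),
       mutated = TRUE)
}

#' Novel mutations in the infinite-sites model
#'
#' The number of new mutations per individual and generation is Poisson
#' distributed with mean `U` (the genome-wide rate, `U = L * mu` in the limit
#' `L -> Inf`, `mu -> 0`).  Every mutation is novel -- it receives a fresh,
#' never-reused identifier and a uniform genomic position in `[0, 1)` -- and
#' back mutations cannot occur.
#'
#' @param g A [mutation_set()].
#' @param U Genome-wide mutation rate (`>= 0`).
#' @param next_id The next unused mutation identifier (monotone counter).
#' @return A list with elements `genotype`, `mutated`, and the updated
#'   `next_id`.
#' @export
mutate_infinite <- function(g, U, next_id = 1L) {
  stopifnot(inherits(g, "mutation_set"), U >= 0, next_id >= 1)
  k <- stats::rpois(1L, U)
  if (k == 0L) return(list(genotype = g, mutated = FALSE, next_id = next_id))
  ids <- seq.int(next_id, length.out = k)
  list(genotype = mutation_set(c(g$ids, ids), c(g$pos, stats::runif(k))),
       mutated = TRUE, next_id = next_id + k)
}
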