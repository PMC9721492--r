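#' Finite-sites genotype
#'
#' A haploid genotype with `L` diallelic loci, stored as the integer index of
#' a vertex of the `L`-dimensional hypercube: bit `i` (0-based) of `index`
#' encodes the allele at locus `i + 1` via \eqn{\{0, 1\} \mapsto \{-1, +1\}}.
#'
#' @param index Integer in `[0, 2^L)`.
#' @param L Number of loci (`>= 1`).
#' @return An object of class `finite_genotype`: an integer with attribute `L`.
#' @examples
#' g <- finite_genotype(5, L = 4)   # alleles (+1, -1, +1, -1)
#' decode_genotype(g)
#' @export
finite_genotype <- function(index, L) {
  L <- as.integer(L)
  index <- as.integer(index)
  stopifnot(length(index) == 1L, length(L) == 1L, L >= 1L)
  if (is.na(index) || index < 0L || index >= bitwShiftL(1L, L)) {
    stop("'index' must lie in [0, 2^L)")
  }
  structure(index, L = L, class = "finite_genotype")
}

#' @export
print.finite_genotype <- function(x, ...) {
  cat(sprintf("<finite_genotype L=%d index=%d  %s>\n", attr(x, "L"),
              unclass(x)[1L], paste(ifelse(decode_genotype(x) > 0, "+", "-"),
                                    collapse = "")))
  invisible(x)
}

#' Decode a genotype index into an allele vector
#'
#' @param g A [finite_genotype()].
#' @return Integer vector of length `L` with entries in `{-1, +1}`.
#' @export
decode_genotype <- function(g) {
  L <- attr(g, "L")
  bits <- bitwAnd(bitwShiftR(unclass(g)[1L], 0:(L - 1L)), 1L)
  2L * bits - 1L
}

#' Encode an allele vector as a genotype
#'
#' @param alleles Vector of length `L` with entries in `{-1, +1}` (or `{0, 1}`).
#' @return A [finite_genotype()].
#' @export
encode_genotype <- function(alleles) {
  L <- length(alleles)
  bits <- as.integer(alleles > 0)
  finite_genotype(sum(bitwShiftL(bits, 0:(L - 1L))), L)
}

# popcount of a vector of non-negative integers with at most `L` relevant bits
popcount <- function(x, L) {
  n <- integer(length(x))
  for (k in 0:(L - 1L)) n <- n + bitwAnd(bitwShiftR(x, k), 1L)
  n
}

#' Hamming distance between two genotypes
#'
#' The number of loci at which two genotypes of equal length differ, i.e. the
#' number of point mutations separating them.
#'
#' @param a,b [finite_genotype()] objects with the same `L`.
#' @return Integer distance in `[0, L]`.
#' @export
hamming_distance <- function(a, b) {
  La <- attr(a, "L"); Lb <- attr(b, "L")
  if (is.null(La) || is.null(Lb) || La != Lb) {
    stop("incompatible genotypes: locus counts differ")
  }
  popcount(bitwXor(unclass(a)[1L], unclass(b)[1L]), La)
}

#' Single-mutant neighbors of a genotype
#'
#' @param g A [finite_genotype()].
#' @return List of the `L` genotypes at Hamming distance 1 from `g`, in the
#'   deterministic order flip locus 1, ..., flip locus `L`.
#' @export
neighbors <- function(g) {
  L <- attr(g, "L")
  idx <- bitwXor(unclass(g)[1L], bitwShiftL(1L, 0:(L - 1L)))
  lapply(idx, finite_genotype, L = L)
}

# neighbor indices of plain integer indices (vectorized over x); used by the
# hot paths that avoid the object wrapper
neighbor_indices <- function(x, L) {
  vapply(0:(L - 1L), function(k) bitwXor(x, bitwShiftL(1L, k)),
         integer(length(x)))
}

#' Infinite-sites genotype: a set of novel mutations
#'
#' In the infinite-sites model a genotype is the set of novel mutations an
#' individual has acquired relative to the ancestral background of fixed
#' mutations.  Each mutation carries a globally unique integer identifier and
#' a genomic position in `[0, 1)` (only used by one-point and Poisson
#' crossover).
#'
#' @param ids Integer vector of mutation identifiers (duplicates forbidden).
#' @param pos Numeric vector of positions in `[0, 1)`, aligned with `ids`.
#'   Defaults to `NA` positions when crossover never needs them.
#' @return An object of class `mutation_set` with sorted `ids`.
#' @export
mutation_set <- function(ids = integer(0), pos = rep(NA_real_, length(ids))) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("duplicate mutation identifiers")
  if (length(pos) != length(ids)) stop("'pos' must align with 'ids'")
  o <- order(ids)
  structure(list(ids = ids[o], pos = as.numeric(pos)[o]),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("<mutation_set {%s}>\n", paste(x$ids, collapse = ",")))
  invisible(x)
}

#' Size of the symmetric difference of two mutation sets
#'
#' The infinite-sites Hamming distance between two individuals.
#'
#' @param a,b [mutation_set()] objects.
#' @return Integer count of mutations private to one of the two sets.
#' @export
mutation_set_distance <- function(a, b) {
  length(a$ids) + length(b$ids) - 2L * sum(a$ids %in% b$ids)
}
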