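#' Crossover operators
#'
#' Three recombination operators shared by all selection schemes, each defined
#' for both genotype representations:
#'
#' * **uniform**: at each locus the offspring copies the allele of one of the
#'   two parents with equal probability.  In the infinite-sites representation
#'   the per-locus rule restricted to segregating sites: mutations shared by
#'   both parents are always inherited, mutations private to one parent are
#'   inherited with probability 1/2.
#' * **one-point**: a single cut position is drawn (uniform on the `L - 1`
#'   interior boundaries for finite sites; uniform on `[0, 1)` for infinite
#'   sites, where every mutation carries a genomic position) and the offspring
#'   takes the first parent's material before the cut and the second parent's
#'   from the cut onwards.
#' * **obligate Poisson**: the number of crossover points is Poisson
#'   distributed with mean `mean_crossovers`; the source parent alternates
#'   across the resulting segments, starting from a fair coin.  Zero crossover
#'   points return one parent wholesale (fair coin).  This operator models
#'   obligate sexual reproduction, where the recombination-rate parameter is
#'   the mean number of crossovers rather than a probability of recombining.
#'
#' @param a,b Two parent genotypes of the same representation: either
#'   [finite_genotype()]s with equal `L`, or [mutation_set()]s (one-point and
#'   Poisson crossover require positions on every mutation).
#' @param mean_crossovers Mean of the Poisson number of crossover points
#'   (`>= 0`).
#' @return A genotype of the same class as the parents.
#' @name crossover
NULL

# ---- finite-sites primitives on raw integer indices ----

rand_bitmask <- function(L) {
  # a uniform integer in [0, 2^L) is L iid fair bits
  as.integer(stats::runif(1) * bitwShiftL(1L, L))
}

# loci with bit set in `mask` come from a, the rest from b
apply_mask_fsm <- function(a, b, mask, L) {
  full <- bitwShiftL(1L, L) - 1L
  bitwOr(bitwAnd(a, mask), bitwAnd(b, bitwAnd(bitwNot(mask), full)))
}

xover_uniform_fsm <- function(a, b, L) {
  apply_mask_fsm(a, b, rand_bitmask(L), L)
}

xover_uniform_fsm_pair <- function(a, b, L) {
  mask <- rand_bitmask(L)
  c(apply_mask_fsm(a, b, mask, L), apply_mask_fsm(b, a, mask, L))
}

# cut k in 1..L-1: loci 1..k from a, loci k+1..L from b
onepoint_mask <- function(L, k = NULL) {
  if (L < 2L) stop("one-point crossover requires L >= 2 (no interior cut)")
  if (is.null(k)) k <- sample.int(L - 1L, 1L)
  bitwShiftL(1L, k) - 1L
}

xover_onepoint_fsm <- function(a, b, L) {
  apply_mask_fsm(a, b, onepoint_mask(L), L)
}

xover_onepoint_fsm_pair <- function(a, b, L) {
  mask <- onepoint_mask(L)
  c(apply_mask_fsm(a, b, mask, L), apply_mask_fsm(b, a, mask, L))
}

# mask of loci sourced from the "start" parent given cut boundaries;
# cuts take values in 1..L-1, a cut at k separates loci 1..k from k+1..L
poisson_mask_fsm <- function(L, rate) {
  ncut <- stats::rpois(1L, rate)
  start_a <- stats::runif(1L) < 0.5
  if (ncut == 0L || L < 2L) {
    mask <- if (start_a) bitwShiftL(1L, L) - 1L else 0L
    return(mask)
  }
  cuts <- sample.int(L - 1L, ncut, replace = TRUE)
  flips <- vapply(1:L, function(i) sum(cuts < i) %% 2L, integer(1))
  from_a <- xor(rep(start_a, L), flips == 1L)
  if (!any(from_a)) 0L else sum(bitwShiftL(1L, which(from_a) - 1L))
}

xover_poisson_fsm <- function(a, b, L, rate) {
  apply_mask_fsm(a, b, poisson_mask_fsm(L, rate), L)
}

xover_poisson_fsm_pair <- function(a, b, L, rate) {
  mask <- poisson_mask_fsm(L, rate)
  c(apply_mask_fsm(a, b, mask, L), apply_mask_fsm(b, a, mask, L))
}

# ---- infinite-sites primitives on raw id vectors ----

# ism children are plain id vectors; canonical (sorted) order is only imposed
# by ism_key(), so the primitives below do not sort

xover_uniform_ism <- function(aids, bids) {
  in_b <- aids %in% bids
  shared <- aids[in_b]
  private <- c(aids[!in_b], bids[!(bids %in% aids)])
  c(shared, private[stats::runif(length(private)) < 0.5])
}

# each private mutation goes to exactly one of the two complementary children
xover_uniform_ism_pair <- function(aids, bids) {
  in_b <- aids %in% bids
  shared <- aids[in_b]
  private <- c(aids[!in_b], bids[!(bids %in% aids)])
  to_first <- stats::runif(length(private)) < 0.5
  list(c(shared, private[to_first]), c(shared, private[!to_first]))
}

xover_onepoint_ism <- function(aids, apos, bids, bpos, x = NULL) {
  if (is.null(x)) x <- stats::runif(1L)
  c(aids[apos < x], bids[bpos >= x])
}

xover_onepoint_ism_pair <- function(aids, apos, bids, bpos) {
  x <- stats::runif(1L)
  list(c(aids[apos < x], bids[bpos >= x]),
       c(bids[bpos < x], aids[apos >= x]))
}

# segment parity of positions given sorted cut points
poisson_segments_ism <- function(rate) {
  ncut <- stats::rpois(1L, rate)
  list(cuts = if (ncut > 0L) sort.int(stats::runif(ncut)) else numeric(0),
       start_a = stats::runif(1L) < 0.5)
}

take_from_a <- function(pos, cuts, start_a) {
  if (length(cuts) == 0L) return(rep(start_a, length(pos)))
  xor(rep(start_a, length(pos)), findInterval(pos, cuts) %% 2L == 1L)
}

xover_poisson_ism <- function(aids, apos, bids, bpos, rate) {
  seg <- poisson_segments_ism(rate)
  c(aids[take_from_a(apos, seg$cuts, seg$start_a)],
    bids[!take_from_a(bpos, seg$cuts, seg$start_a)])
}

xover_poisson_ism_pair <- function(aids, apos, bids, bpos, rate) {
  seg <- poisson_segments_ism(rate)
  a_first <- take_from_a(apos, seg$cuts, seg$start_a)
  b_first <- !take_from_a(bpos, seg$cuts, seg$start_a)
  list(c(aids[a_first], bids[b_first]),
       c(aids[!a_first], bids[!b_first]))
}

# ---- user-facing operators on genotype objects ----

check_parents <- function(a, b) {
  if (inherits(a, "finite_genotype") && inherits(b, "finite_genotype")) {
    if (attr(a, "L") != attr(b, "L")) {
      stop("incompatible genotypes: locus counts differ")
    }
    return("finite")
  }
  if (inherits(a, "mutation_set") && inherits(b, "mutation_set")) {
    return("infinite")
  }
  stop("parents must both be finite_genotype or both mutation_set")
}

ms_subset <- function(a, b, ids) {
  pos <- c(a$pos, b$pos)[match(ids, c(a$ids, b$ids))]
  mutation_set(ids, pos)
}

#' @rdname crossover
#' @export
crossover_uniform <- function(a, b) {
  if (check_parents(a, b) == "finite") {
    L <- attr(a, "L")
    finite_genotype(xover_uniform_fsm(unclass(a)[1L], unclass(b)[1L], L), L)
  } else {
    ms_subset(a, b, xover_uniform_ism(a$ids, b$ids))
  }
}

#' @rdname crossover
#' @export
crossover_one_point <- function(a, b) {
  if (check_parents(a, b) == "finite") {
    L <- attr(a, "L")
    finite_genotype(xover_onepoint_fsm(unclass(a)[1L], unclass(b)[1L], L), L)
  } else {
    ms_subset(a, b, xover_onepoint_ism(a$ids, a$pos, b$ids, b$pos))
  }
}

#' @rdname crossover
#' @export
crossover_obligate_poisson <- function(a, b, mean_crossovers) {
  stopifnot(mean_crossovers >= 0)
  if (check_parents(a, b) == "finite") {
    L <- attr(a, "L")
    finite_genotype(
      xover_poisson_fsm(unclass(a)[1L], unclass(b)[1L], L, mean_crossovers), L)
  } else {
    ms_subset(a, b,
              xover_poisson_ism(a$ids, a$pos, b$ids, b$pos, mean_crossovers))
  }
}
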