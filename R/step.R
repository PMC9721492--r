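#' One Wright-Fisher generation
#'
#' Advances a population by a single discrete, non-overlapping generation of
#' size-`N` Wright-Fisher dynamics under the configured selection-recombination
#' scheme, then applies mutation to every offspring and re-evaluates fitness.
#' The fixed order of operations is selection/recombination, then mutation,
#' then fitness evaluation; all observables are meant to be measured after the
#' mutation step.
#'
#' Schemes (all keep the population size exactly `N`):
#'
#' * `concurrent`: each offspring independently is recombinant with
#'   probability `r`, in which case two *distinct* parent slots are drawn with
#'   probability proportional to fitness and crossed over; otherwise a single
#'   fitness-proportional parent is copied.
#' * `successive_simple`: a pure fitness-proportional resampling first
#'   produces `N` survivors; each offspring is then, with probability `r`,
#'   replaced by a crossover of two distinct survivors drawn uniformly
#'   (fitness-blind).  The second sampling layer makes genetic drift depend
#'   on `r`.
#' * `successive_pairs`: after the survivor step, each survivor is marked
#'   recombining with probability `r`; marked survivors are paired uniformly
#'   at random and each pair produces two complementary offspring (at every
#'   segregating locus one child carries the first parent's allele and the
#'   other child the second parent's), so allele counts pass through the
#'   recombination stage unchanged.  An unpaired leftover survivor passes
#'   through clonally.
#'
#' Under `crossover = "obligate_poisson"` every offspring recombines and `r`
#' is the mean number of crossover points.
#'
#' If a recombinant offspring needs two distinct parents but only one slot is
#' available (a single individual with nonzero fitness, or `N = 1`), it is
#' produced clonally and *not* counted as a recombination event.
#'
#' @param pop A [new_population()] object.
#' @param cfg The [sim_config()] used to create it.
#' @param world The `percolation_landscape` or [ism_oracle()].
#' @return The next-generation `wf_population`; its `$tally` holds the
#'   per-generation event counts `mutation_events`, `recombination_events`,
#'   `viable_recombinants` (recombinants whose pre-mutation product is
#'   viable), and placeholders `novel_viable_discoveries` /`fixations` that
#'   the bookkeeping helpers [update_discovery()] and
#'   [detect_and_purge_fixations()] fill in.
#' @seealso [run_stationary()] for a complete measurement loop.
#' @export
wf_step <- function(pop, cfg, world) {
  stopifnot(inherits(pop, "wf_population"), inherits(cfg, "sim_config"),
            pop$representation == cfg$representation)
  w <- pop$fitness
  if (all(w == 0)) {
    extinction_error(pop$generation)
  }
  finite <- pop$representation == "finite"
  genomes <- if (finite) pop$geno else pop$sets
  res <- switch(cfg$scheme,
    concurrent = offspring_concurrent(genomes, w, cfg, pop),
    successive_simple = offspring_successive_simple(genomes, w, cfg, pop),
    successive_pairs = offspring_successive_pairs(genomes, w, cfg, pop))
  children <- res$children
  rec_slots <- res$rec_slots

  # recombinant viability is judged on the pre-mutation product
  rec_keys <- NULL
  rec_viab <- NULL
  if (length(rec_slots) == 0L) {
    viable_rec <- 0L
  } else if (finite) {
    viable_rec <- sum(world$viability[unlist(children[rec_slots]) + 1L])
  } else {
    rec_keys <- vapply(children[rec_slots], ism_key, character(1))
    rec_viab <- oracle_viability_keys(world, rec_keys)
    viable_rec <- sum(rec_viab)
  }

  if (finite) {
    mut <- mutate_children_fsm(unlist(children), cfg)
    geno <- mut$geno
    fitness <- ifelse(world$viability[geno + 1L], 1, world$w0)
    out <- pop
    out$geno <- geno
  } else {
    mut <- mutate_children_ism(children, cfg, pop$next_id)
    # genotypes of unmutated clonal offspring are unchanged: their canonical
    # keys and (write-once) cached fitness are inherited from the parent,
    # only recombinant or mutated offspring need an oracle lookup
    mutated <- logical(pop$N)
    mutated[mut$mutated_slots] <- TRUE
    recombinant <- logical(pop$N)
    recombinant[rec_slots] <- TRUE
    keys <- character(pop$N)
    fitness <- numeric(pop$N)
    clonal <- !recombinant & !mutated
    src_keys <- get_keys(pop)
    keys[clonal] <- src_keys[res$src[clonal]]
    fitness[clonal] <- pop$fitness[res$src[clonal]]
    # unmutated recombinants keep the pre-mutation product already evaluated
    keep_rec <- recombinant & !mutated
    if (any(keep_rec)) {
      at <- match(which(keep_rec), rec_slots)
      keys[keep_rec] <- rec_keys[at]
      fitness[keep_rec] <- ifelse(rec_viab[at], 1, cfg$w0)
    }
    if (any(mutated)) {
      keys[mutated] <- vapply(mut$children[mutated], ism_key, character(1))
      fitness[mutated] <- ifelse(
        oracle_viability_keys(world, keys[mutated]), 1, cfg$w0)
    }
    out <- pop
    out$sets <- mut$children
    out$keys <- keys
    out$pos <- c(pop$pos, mut$new_pos)
    out$next_id <- mut$next_id
  }
  out$fitness <- fitness
  out$generation <- pop$generation + 1L
  out$tally <- list(mutation_events = mut$mutation_events,
                    recombination_events = length(rec_slots),
                    viable_recombinants = viable_rec,
                    novel_viable_discoveries = NA_integer_,
                    fixations = NA_integer_)
  out
}

extinction_error <- function(generation) {
  cond <- simpleError(sprintf(
    "population went extinct: all individuals unfit at generation %d",
    generation))
  class(cond) <- c("extinction_error", class(cond))
  cond$generation <- generation
  stop(cond)
}

wsample <- function(w, n) {
  sample.int(length(w), n, replace = TRUE, prob = w)
}

# n pairs of distinct parent slots, each slot drawn with probability
# proportional to w; the second draw is conditioned on differing from the
# first (vectorized rejection, equivalent to zeroing the first slot's weight)
draw_distinct_pairs <- function(w, n) {
  first <- wsample(w, n)
  second <- wsample(w, n)
  repeat {
    bad <- second == first
    if (!any(bad)) break
    second[bad] <- wsample(w, sum(bad))
  }
  list(first = first, second = second)
}

# crossover closure on raw genotypes for the configured operator;
# `pair = TRUE` yields the complementary two-child version
make_cross <- function(cfg, pop, pair = FALSE) {
  if (cfg$representation == "finite") {
    L <- pop$L
    if (!pair) {
      switch(cfg$crossover,
        uniform = function(a, b) xover_uniform_fsm(a, b, L),
        one_point = function(a, b) xover_onepoint_fsm(a, b, L),
        obligate_poisson = function(a, b) xover_poisson_fsm(a, b, L, cfg$r))
    } else {
      switch(cfg$crossover,
        uniform = function(a, b) xover_uniform_fsm_pair(a, b, L),
        one_point = function(a, b) xover_onepoint_fsm_pair(a, b, L),
        obligate_poisson = function(a, b)
          xover_poisson_fsm_pair(a, b, L, cfg$r))
    }
  } else {
    pos <- pop$pos
    if (!pair) {
      switch(cfg$crossover,
        uniform = function(a, b) xover_uniform_ism(a, b),
        one_point = function(a, b)
          xover_onepoint_ism(a, pos[a], b, pos[b]),
        obligate_poisson = function(a, b)
          xover_poisson_ism(a, pos[a], b, pos[b], cfg$r))
    } else {
      switch(cfg$crossover,
        uniform = function(a, b) xover_uniform_ism_pair(a, b),
        one_point = function(a, b)
          xover_onepoint_ism_pair(a, pos[a], b, pos[b]),
        obligate_poisson = function(a, b)
          xover_poisson_ism_pair(a, pos[a], b, pos[b], cfg$r))
    }
  }
}

recombination_flags <- function(cfg, N) {
  if (cfg$crossover == "obligate_poisson") rep(TRUE, N)
  else stats::runif(N) < cfg$r
}

# children are returned as a list of raw genotypes in all cases; rec_slots
# are the offspring slots actually produced by recombination, and src maps
# each non-recombinant offspring to its parent slot (NA for recombinants)
offspring_concurrent <- function(genomes, w, cfg, pop) {
  N <- length(w)
  if (!is.list(genomes)) genomes <- as.list(genomes)
  rec <- recombination_flags(cfg, N)
  can_pair <- sum(w > 0) >= 2L
  cross <- make_cross(cfg, pop)
  children <- vector("list", N)
  src <- rep(NA_integer_, N)
  clonal <- which(!rec | !can_pair)
  if (length(clonal)) {
    par <- wsample(w, length(clonal))
    children[clonal] <- genomes[par]
    src[clonal] <- par
  }
  rec_slots <- which(rec & can_pair)
  if (length(rec_slots)) {
    pr <- draw_distinct_pairs(w, length(rec_slots))
    for (i in seq_along(rec_slots)) {
      children[[rec_slots[i]]] <- cross(genomes[[pr$first[i]]],
                                        genomes[[pr$second[i]]])
    }
  }
  list(children = children, rec_slots = rec_slots, src = src)
}

offspring_successive_simple <- function(genomes, w, cfg, pop) {
  N <- length(w)
  if (!is.list(genomes)) genomes <- as.list(genomes)
  surv <- wsample(w, N)
  pool <- genomes[surv]
  rec <- recombination_flags(cfg, N)
  if (N < 2L) rec[] <- FALSE
  cross <- make_cross(cfg, pop)
  children <- pool
  src <- surv
  rec_slots <- which(rec)
  if (length(rec_slots)) {
    # two distinct pool slots per recombinant, fitness-blind
    pr <- draw_distinct_pairs(rep(1, N), length(rec_slots))
    for (i in seq_along(rec_slots)) {
      children[[rec_slots[i]]] <- cross(pool[[pr$first[i]]],
                                        pool[[pr$second[i]]])
    }
    src[rec_slots] <- NA_integer_
  }
  list(children = children, rec_slots = rec_slots, src = src)
}

offspring_successive_pairs <- function(genomes, w, cfg, pop) {
  N <- length(w)
  if (!is.list(genomes)) genomes <- as.list(genomes)
  surv <- wsample(w, N)
  pool <- genomes[surv]
  mark <- recombination_flags(cfg, N)
  if (N < 2L) mark[] <- FALSE
  children <- pool
  src <- surv
  mk <- which(mark)
  rec_slots <- integer(0)
  if (length(mk) >= 2L) {
    cross2 <- make_cross(cfg, pop, pair = TRUE)
    perm <- mk[sample.int(length(mk))]
    npair <- length(mk) %/% 2L
    for (i in seq_len(npair)) {
      a <- perm[2L * i - 1L]
      b <- perm[2L * i]
      ch <- cross2(pool[[a]], pool[[b]])
      children[[a]] <- ch[[1L]]
      children[[b]] <- ch[[2L]]
    }
    rec_slots <- perm[seq_len(2L * npair)]   # an odd leftover stays clonal
    src[rec_slots] <- NA_integer_
  }
  list(children = children, rec_slots = rec_slots, src = src)
}

mutate_children_fsm <- function(geno, cfg) {
  N <- length(geno)
  nf <- stats::rbinom(N, cfg$L, cfg$mu)
  for (j in which(nf > 0L)) {
    loci <- sample.int(cfg$L, nf[j])
    geno[j] <- bitwXor(geno[j], sum(bitwShiftL(1L, loci - 1L)))
  }
  list(geno = geno, mutation_events = sum(nf > 0L))
}

mutate_children_ism <- function(children, cfg, next_id) {
  N <- length(children)
  k <- stats::rpois(N, cfg$U)
  tot <- sum(k)
  if (tot == 0L) {
    return(list(children = children, new_pos = numeric(0), next_id = next_id,
                mutation_events = 0L, mutated_slots = integer(0)))
  }
  new_pos <- stats::runif(tot)
  ends <- cumsum(k)
  mutated_slots <- which(k > 0L)
  for (j in mutated_slots) {
    ids <- seq.int(next_id + ends[j] - k[j], length.out = k[j])
    children[[j]] <- c(children[[j]], ids)
  }
  list(children = children, new_pos = new_pos, next_id = next_id + tot,
       mutation_events = length(mutated_slots),
       mutated_slots = mutated_slots)
}
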