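#' Population observables
#'
#' Measures of diversity, evolvability, robustness, and fitness, all meant to
#' be evaluated at the end of a generation (after the mutation step).
#' Individuals with fitness exactly 1 are the viable ones (`w0 < 1` always);
#' the diversity measures `pairwise_mean_hamming()` and
#' `segregating_mutations()` include unfit individuals, whereas
#' `distinct_viable_genotypes()` counts viable individuals only and
#' `mutational_robustness()` scores unfit individuals as 0.
#'
#' @param pop A `wf_population`.
#' @name observables
NULL

viable_mask <- function(pop) pop$fitness == 1

#' @describeIn observables Mean Hamming distance over all ordered pairs of
#'   distinct individuals (equivalently unordered, by symmetry).  In the
#'   infinite-sites representation the distance between two individuals is the
#'   size of the symmetric difference of their mutation sets.
#' @export
pairwise_mean_hamming <- function(pop) {
  N <- pop$N
  if (N < 2L) stop("pairwise mean Hamming distance requires N >= 2")
  if (pop$representation == "finite") {
    d <- popcount(outer(pop$geno, pop$geno, bitwXor), pop$L)
    sum(d) / (N * (N - 1))
  } else {
    ids <- sort.int(unique(unlist(pop$sets)))
    if (length(ids) == 0L) return(0)
    M <- vapply(pop$sets, function(s) ids %in% s, logical(length(ids)))
    M <- matrix(as.numeric(M), nrow = length(ids))
    sz <- colSums(M)
    shared <- crossprod(M)
    d <- outer(sz, sz, `+`) - 2 * shared
    sum(d) / (N * (N - 1))
  }
}

#' @describeIn observables Number of distinct genotypes among viable
#'   individuals.
#' @export
distinct_viable_genotypes <- function(pop) {
  v <- viable_mask(pop)
  if (!any(v)) return(0L)
  if (pop$representation == "finite") {
    length(unique(pop$geno[v]))
  } else {
    length(unique(get_keys(pop)[v]))
  }
}

#' @describeIn observables Number of segregating mutations: loci at which both
#'   alleles are present in the population (finite sites), or mutation
#'   identifiers carried by at least 1 but at most `N - 1` individuals
#'   (infinite sites; identifiers present in all `N` individuals are fixation
#'   candidates and are counted until [detect_and_purge_fixations()] removes
#'   them).
#' @export
segregating_mutations <- function(pop) {
  if (pop$representation == "finite") {
    N <- pop$N
    ones <- vapply(0:(pop$L - 1L),
                   function(k) sum(bitwAnd(bitwShiftR(pop$geno, k), 1L)),
                   numeric(1))
    sum(ones > 0 & ones < N)
  } else {
    cnt <- table(unlist(pop$sets))
    sum(cnt >= 1L & cnt <= pop$N - 1L)
  }
}

#' @describeIn observables Mean over all individuals of the genotype
#'   robustness (fraction of viable single-mutant neighbors; 0 for unfit
#'   individuals).  Defined for the finite-sites representation only: in the
#'   infinite-sites limit almost all neighbors are undiscovered, so the
#'   measure is undefined.
#' @param landscape The `percolation_landscape` the population evolves on.
#' @export
mutational_robustness <- function(pop, landscape) {
  if (pop$representation != "finite") {
    stop("mutational robustness is undefined in the infinite-sites model")
  }
  mean(robustness_indices(landscape, pop$geno))
}

#' @describeIn observables Arithmetic mean of individual fitness values.
#' @export
mean_fitness <- function(pop) {
  mean(pop$fitness)
}

#' @describeIn observables Per-individual number of segregating mutations,
#'   i.e. each individual's Hamming distance to the ancestral genotype
#'   carrying only fixed mutations (infinite sites).
#' @export
individual_mutation_counts <- function(pop) {
  if (pop$representation != "finite") return(lengths(pop$sets))
  stop("individual mutation counts relative to the fixed background are ",
       "defined in the infinite-sites model only")
}

#' Track the discovery of novel viable genotypes
#'
#' A discovery tracker records every viable genotype that has ever been
#' present in at least one individual.  Full discovery (finite sites) is
#' reached when all viable genotypes of the landscape have been seen.  The
#' initial genotype counts as discovered at generation 0.
#'
#' @param world A `percolation_landscape` or [ism_oracle()].
#' @return An object of class `discovery_tracker` (environment, reference
#'   semantics).
#' @export
discovery_tracker <- function(world) {
  tr <- new.env(parent = emptyenv())
  if (inherits(world, "percolation_landscape")) {
    tr$representation <- "finite"
    tr$seen <- logical(length(world$viability))
    tr$first_hit <- rep(NA_integer_, length(world$viability))
    tr$total_viable <- sum(world$viability)
    tr$n_seen <- 0L
  } else {
    tr$representation <- "infinite"
    tr$seen <- new.env(hash = TRUE, parent = emptyenv())
    tr$n_seen <- 0L
    tr$total_viable <- NA_integer_
  }
  class(tr) <- "discovery_tracker"
  tr
}

#' @export
print.discovery_tracker <- function(x, ...) {
  cat(sprintf("<discovery_tracker %s  %s viable genotypes seen>\n",
              x$representation,
              if (is.na(x$total_viable)) x$n_seen
              else sprintf("%d/%d", x$n_seen, x$total_viable)))
  invisible(x)
}

#' Record the viable genotypes present in a population
#'
#' Adds all never-before-seen viable genotypes present in `pop` (judged on the
#' post-mutation population, so transient crossover products destroyed by
#' mutation in the same generation do not count) and returns the number added
#' -- the per-generation discovery increment whose long-run average is the
#' discovery rate.
#'
#' @param tracker A [discovery_tracker()].
#' @param pop The `wf_population` measured after the mutation step.
#' @param generation Generation index recorded as the first-hit time.
#' @return Integer count of novel viable genotypes this generation.
#' @export
update_discovery <- function(tracker, pop, generation = pop$generation) {
  v <- viable_mask(pop)
  if (!any(v)) return(0L)
  if (tracker$representation == "finite") {
    idx <- unique(pop$geno[v])
    new <- idx[!tracker$seen[idx + 1L]]
    tracker$seen[new + 1L] <- TRUE
    tracker$first_hit[new + 1L] <- generation
    tracker$n_seen <- tracker$n_seen + length(new)
    length(new)
  } else {
    keys <- unique(get_keys(pop)[v])
    n_new <- 0L
    for (k in keys) {
      if (is.null(tracker$seen[[k]])) {
        tracker$seen[[k]] <- generation
        n_new <- n_new + 1L
      }
    }
    tracker$n_seen <- tracker$n_seen + n_new
    n_new
  }
}

#' Has every viable genotype been discovered?
#'
#' @param tracker A finite-sites [discovery_tracker()].
#' @return Logical.
#' @export
full_discovery <- function(tracker) {
  if (tracker$representation != "finite") {
    stop("full discovery is defined for finite-sites landscapes only")
  }
  tracker$n_seen == tracker$total_viable
}

# rewrite the tracker's seen-set after `fixed_id` joins the background:
# keys lacking the fixed mutation can never recur (no back mutations)
tracker_purge_fixation <- function(tracker, fixed_id) {
  if (tracker$representation != "infinite") return(invisible(tracker))
  seen <- tracker$seen
  keys <- ls(seen, sorted = FALSE)
  reb <- rebase_keys(keys, fixed_id)
  rm(list = keys[!reb$keep], envir = seen)   # drop before rebasing (collisions)
  if (any(reb$keep)) {
    gens <- mget(keys[reb$keep], envir = seen)
    rm(list = keys[reb$keep], envir = seen)
    for (i in seq_along(gens)) seen[[reb$new[i]]] <- gens[[i]]
  }
  invisible(tracker)
}

#' Detect fixed mutations and purge them from population and oracle
#'
#' A mutation present in all `N` individuals is fixed: due to the absence of
#' back mutations it can be absorbed into the ancestral background.  Each
#' fixed identifier is removed from every individual's mutation set, the
#' oracle cache is purged via [purge_on_fixation()], and an optional discovery
#' tracker is rewritten accordingly.
#'
#' @param pop An infinite-sites `wf_population`.
#' @param oracle The [ism_oracle()] of the run.
#' @param tracker Optional [discovery_tracker()] to keep consistent.
#' @return A list with the updated `population` and the integer vector
#'   `fixed_ids` (its length is the per-generation fixation count whose
#'   long-run average is the fixation rate).
#' @export
detect_and_purge_fixations <- function(pop, oracle, tracker = NULL) {
  if (pop$representation == "finite") {
    stop("fixation purging applies to the infinite-sites model only")
  }
  # a fixed mutation must be carried by individual 1, so only its mutations
  # are candidates; scan the rest of the population with early exit
  candidates <- pop$sets[[1L]]
  fixed <- integer(0)
  for (id in candidates) {
    carried_by_all <- TRUE
    for (j in seq_len(pop$N)[-1L]) {
      if (!(id %in% pop$sets[[j]])) {
        carried_by_all <- FALSE
        break
      }
    }
    if (carried_by_all) fixed <- c(fixed, id)
  }
  if (length(fixed)) {
    pop$sets <- lapply(pop$sets, function(s) s[!(s %in% fixed)])
    if (!is.null(pop$keys)) {
      pop$keys <- vapply(pop$sets, ism_key, character(1))
    }
    for (id in fixed) {
      purge_on_fixation(oracle, id)
      if (!is.null(tracker)) tracker_purge_fixation(tracker, id)
    }
  }
  list(population = pop, fixed_ids = fixed)
}

#' Empirical cross-section of the population cloud
#'
#' Normalized histogram of per-individual distances to the fixed-background
#' ancestor (the individual mutation-set sizes), accumulated over many
#' generations.  Without recombination the distribution follows the
#' hypoexponential law [hypoexponential_mrca_density()]; at high recombination
#' rates it approaches a Poisson shape.
#'
#' @param samples Integer vector of per-individual segregating-mutation counts
#'   pooled over generations.
#' @return A data frame with columns `distance` and `probability` (summing
#'   to 1).
#' @export
cross_section_histogram <- function(samples) {
  stopifnot(length(samples) > 0, all(samples >= 0))
  tb <- tabulate(samples + 1L, nbins = max(samples) + 1L)
  data.frame(distance = 0:max(samples), probability = tb / sum(tb))
}

#' Fraction of recombination events with a viable product
#'
#' The fraction of recombination events per generation whose immediate
#' (pre-mutation) product is viable, pooled over a window of generation
#' tallies.
#'
#' @param tallies A list of per-generation tallies as produced by
#'   [wf_step()], or a single tally.
#' @return Numeric fraction, or `NA` when no recombination event occurred in
#'   the window (the quantity is then undefined, not 0).
#' @export
viable_recombination_fraction <- function(tallies) {
  if (!is.null(tallies$recombination_events)) tallies <- list(tallies)
  rec <- sum(vapply(tallies, `[[`, numeric(1), "recombination_events"))
  if (rec == 0) return(NA_real_)
  via <- sum(vapply(tallies, `[[`, numeric(1), "viable_recombinants"))
  via / rec
}
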