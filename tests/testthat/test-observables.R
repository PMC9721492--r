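# a small hand-built finite-sites population for measure checks
make_pop <- function(geno, world, cfg) {
  pop <- new_population(cfg, world, start = geno[1])
  pop$geno <- as.integer(geno)
  pop$fitness <- ifelse(world$viability[pop$geno + 1L], 1, world$w0)
  pop
}

test_that("diversity measures evaluate hand-built populations exactly", {
  world <- manual_landscape(rep(TRUE, 8), p = 1)
  cfg <- sim_config(N = 4, L = 3, mu = 0, p = 1)
  mono <- make_pop(rep(5L, 4), world, cfg)
  expect_equal(pairwise_mean_hamming(mono), 0)
  expect_equal(distinct_viable_genotypes(mono), 1L)
  expect_equal(segregating_mutations(mono), 0L)
  expect_equal(mean_fitness(mono), 1)
  cfg2 <- sim_config(N = 2, L = 3, mu = 0, p = 1)
  two <- make_pop(c(0L, 7L), world, cfg2)   # differ at all 3 loci
  expect_equal(pairwise_mean_hamming(two), 3)
  expect_equal(segregating_mutations(two), 3L)
  expect_error(pairwise_mean_hamming(make_pop(0L, world,
    sim_config(N = 1, L = 3, mu = 0, p = 1))), "N >= 2")
})

test_that("viability-aware measures exclude or zero the unfit individuals", {
  viab <- rep(TRUE, 8); viab[8] <- FALSE    # genotype 7 lethal
  world <- manual_landscape(viab)
  cfg <- sim_config(N = 4, L = 3, mu = 0, p = 0.5)
  pop <- make_pop(c(0L, 0L, 7L, 7L), world, cfg)
  expect_equal(distinct_viable_genotypes(pop), 1L)
  expect_equal(mean_fitness(pop), 0.5)
  # unfit individuals still count in the diversity measures
  expect_equal(segregating_mutations(pop), 3L)
  expect_equal(pairwise_mean_hamming(pop), 2)   # 8 of 12 ordered pairs at d=3
  # robustness: genotype 0 has neighbors 1,2,4 all viable; unfit scores 0
  expect_equal(mutational_robustness(pop, world), 0.5)
  allbad <- make_pop(c(7L, 7L, 7L, 7L), world, cfg)
  expect_equal(distinct_viable_genotypes(allbad), 0L)
  expect_equal(mutational_robustness(allbad, world), 0)
})

test_that("infinite-sites measures work on mutation sets and robustness is
           refused", {
  oracle <- ism_oracle(1, seed = 2)
  cfg <- sim_config(N = 3, U = 0, p = 1)
  pop <- new_population(cfg, oracle)
  pop$sets <- list(c(1L, 2L), c(2L, 3L), integer(0))
  pop$keys <- NULL                 # invalidate the cache after a direct edit
  pop$fitness <- rep(1, 3)
  # pairwise symmetric differences: (1,2)-(2,3): 2; (1,2)-(): 2; (2,3)-(): 2
  expect_equal(pairwise_mean_hamming(pop), 2)
  expect_equal(distinct_viable_genotypes(pop), 3L)
  expect_equal(segregating_mutations(pop), 3L)
  expect_equal(individual_mutation_counts(pop), c(2L, 2L, 0L))
  expect_error(mutational_robustness(pop, NULL), "undefined")
})

test_that("the discovery tracker counts first sightings once and reaches full
           discovery", {
  viab <- c(TRUE, TRUE, TRUE, FALSE)
  world <- manual_landscape(viab)
  cfg <- sim_config(N = 3, L = 2, mu = 0, p = 0.5)
  tr <- discovery_tracker(world)
  pop <- make_pop(c(0L, 0L, 0L), world, cfg)
  expect_equal(update_discovery(tr, pop, 0), 1L)   # the initial genotype
  expect_equal(update_discovery(tr, pop, 1), 0L)   # nothing new
  pop2 <- make_pop(c(0L, 1L, 3L), world, cfg)      # 3 is unfit: not discovered
  expect_equal(update_discovery(tr, pop2, 2), 1L)
  expect_false(full_discovery(tr))
  pop3 <- make_pop(c(2L, 1L, 0L), world, cfg)
  expect_equal(update_discovery(tr, pop3, 3), 1L)
  expect_true(full_discovery(tr))
  expect_equal(tr$first_hit[c(1, 2, 3)], c(0L, 2L, 3L))
})

test_that("fixation detection purges population, oracle and tracker
           consistently", {
  oracle <- ism_oracle(1, seed = 5)
  cfg <- sim_config(N = 3, U = 0, p = 1)
  pop <- new_population(cfg, oracle)
  tr <- discovery_tracker(oracle)
  # tau (id 1) carried by everyone, zeta (id 2) segregating
  pop$sets <- list(1L, c(1L, 2L), 1L)
  pop$keys <- NULL
  pop$pos <- c(0.5, 0.25)
  pop$next_id <- 3L
  pop$fitness <- rep(1, 3)
  invisible(ism_fitness(oracle, 1L))
  invisible(ism_fitness(oracle, c(1L, 2L)))
  update_discovery(tr, pop, 1)
  out <- detect_and_purge_fixations(pop, oracle, tr)
  expect_equal(out$fixed_ids, 1L)
  expect_equal(out$population$sets, list(integer(0), 2L, integer(0)))
  expect_false(any(vapply(ls(oracle$cache), function(k) grepl("1", k),
                          logical(1))))
  expect_setequal(ls(tr$seen), c("0", "2"))
  # no fixation when one individual lacks the mutation
  pop2 <- out$population
  expect_length(detect_and_purge_fixations(pop2, oracle, tr)$fixed_ids, 0L)
})

test_that("cross-section histograms are normalized and degenerate at U = 0", {
  h <- cross_section_histogram(c(0L, 0L, 0L))
  expect_equal(h$probability, 1)
  expect_equal(h$distance, 0)
  set.seed(23)
  samples <- stats::rpois(500, 3)
  h2 <- cross_section_histogram(samples)
  expect_equal(sum(h2$probability), 1)
  expect_equal(nrow(h2), max(samples) + 1)
})

test_that("the viable recombination fraction pools tallies and is undefined
           without recombination events", {
  t1 <- list(recombination_events = 10L, viable_recombinants = 7L)
  t2 <- list(recombination_events = 5L, viable_recombinants = 5L)
  expect_equal(viable_recombination_fraction(list(t1, t2)), 12 / 15)
  expect_equal(viable_recombination_fraction(t1), 0.7)
  expect_true(is.na(viable_recombination_fraction(
    list(list(recombination_events = 0L, viable_recombinants = 0L)))))
})

test_that("in the weak-mutation regime the population occupies viable
           genotypes uniformly, irrespective of degree", {
  set.seed(24)
  world <- generate_connected_landscape(4, 0.6)
  viable <- which(world$viability) - 1L
  # make sure the landscape has heterogeneous degrees for the test to bite
  deg <- neutralnets:::robustness_indices(world, viable)
  expect_gt(stats::sd(deg), 0)
  cfg <- sim_config(N = 5, L = 4, mu = 5e-3, r = 0, p = 0.6)  # N*L*mu = 0.1
  pop <- new_population(cfg, world, start = viable[1])
  for (i in seq_len(2e4)) pop <- wf_step(pop, cfg, world)   # burn-in
  occupancy <- integer(length(viable))
  nsamp <- 800
  for (s in seq_len(nsamp)) {
    for (i in seq_len(250)) pop <- wf_step(pop, cfg, world)
    modal <- as.integer(names(which.max(table(pop$geno))))
    occupancy[match(modal, viable)] <- occupancy[match(modal, viable)] + 1L
  }
  gof <- stats::chisq.test(occupancy, p = rep(1 / length(viable),
                                              length(viable)))
  expect_gt(gof$p.value, 0.001)
})
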