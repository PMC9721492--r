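test_that("population size stays exactly N under every scheme, crossover and
           representation", {
  set.seed(14)
  for (scheme in c("concurrent", "successive_simple", "successive_pairs")) {
    for (xo in c("uniform", "one_point", "obligate_poisson")) {
      cfg <- sim_config(N = 21, L = 5, mu = 0.05, r = 0.7, p = 0.8, w0 = 0,
                        scheme = scheme, crossover = xo)
      world <- generate_connected_landscape(5, 0.8)
      pop <- step_n(new_population(cfg, world), cfg, world, 20)
      expect_length(pop$geno, 21L)
      expect_length(pop$fitness, 21L)
      cfg2 <- sim_config(N = 21, U = 0.2, r = 0.7, p = 0.8,
                         scheme = scheme, crossover = xo)
      oracle <- ism_oracle(0.8)
      pop2 <- new_population(cfg2, oracle)
      for (g in 1:20) {
        pop2 <- wf_step(pop2, cfg2, oracle)
        pop2 <- detect_and_purge_fixations(pop2, oracle)$population
      }
      expect_length(pop2$sets, 21L)
    }
  }
})

test_that("unfit individuals are never selected as parents", {
  # N = 2, one viable and one lethal individual, no mutation: both offspring
  # must copy the viable parent, in every scheme
  viab <- c(TRUE, FALSE, TRUE, TRUE)       # genotype 1 (index 1) is unfit
  world <- manual_landscape(viab)
  set.seed(15)
  for (scheme in c("concurrent", "successive_simple", "successive_pairs")) {
    cfg <- sim_config(N = 2, L = 2, mu = 0, r = 0, p = 0.5, scheme = scheme)
    pop <- new_population(cfg, world, start = 0L)
    pop$geno <- c(0L, 1L)
    pop$fitness <- c(1, 0)
    for (i in 1:25) {
      out <- wf_step(pop, cfg, world)
      expect_equal(out$geno, c(0L, 0L))
    }
  }
})

test_that("a monomorphic viable population is invariant under recombination
           without mutation, and every recombinant is viable", {
  set.seed(16)
  world <- generate_connected_landscape(6, 0.6)
  start <- which(world$viability)[1] - 1L
  for (scheme in c("concurrent", "successive_simple", "successive_pairs")) {
    cfg <- sim_config(N = 30, L = 6, mu = 0, r = 1, p = 0.6, scheme = scheme)
    pop <- new_population(cfg, world, start = start)
    out <- wf_step(pop, cfg, world)
    expect_true(all(out$geno == start))
    expect_gt(out$tally$recombination_events, 0)
    expect_equal(out$tally$viable_recombinants,
                 out$tally$recombination_events)
  }
  # infinite sites likewise
  oracle <- ism_oracle(0.6)
  cfg <- sim_config(N = 30, U = 0, r = 1, p = 0.6)
  pop <- new_population(cfg, oracle)
  out <- wf_step(pop, cfg, oracle)
  expect_true(all(lengths(out$sets) == 0))
  expect_equal(out$tally$viable_recombinants, out$tally$recombination_events)
})

test_that("without recombination the three schemes produce identically
           distributed allele counts", {
  set.seed(17)
  counts <- lapply(c("concurrent", "successive_simple", "successive_pairs"),
                   allele_count_one_gen, r = 0, N = 100L, nreps = 2000L)
  vars <- vapply(counts, stats::var, numeric(1))
  # one-generation Wright-Fisher drift from frequency 1/2: variance N/4
  se_var <- sqrt(2 / 2000) * 25
  for (v in vars) expect_lt(abs(v - 25), 3 * se_var)
  for (cnt in counts) expect_lt(abs(mean(cnt) - 50), 3 * sqrt(25 / 2000))
})

test_that("recombination adds drift in the simple successive scheme but not
           in the concurrent scheme", {
  set.seed(18)
  v_conc <- stats::var(allele_count_one_gen("concurrent", 1, nreps = 2000L))
  v_simp <- stats::var(allele_count_one_gen("successive_simple", 1,
                                            nreps = 2000L))
  se_var <- sqrt(2 / 2000) * 25
  expect_lt(abs(v_conc - 25), 3 * se_var)
  expect_gt(v_simp, 25 + 3 * se_var * sqrt(2))  # two sampling layers
})

test_that("infinite-sites bookkeeping never reuses identifiers and keeps sets
           consistent with the fixed background", {
  set.seed(19)
  cfg <- sim_config(N = 25, U = 0.3, r = 0.5, p = 0.7)
  oracle <- ism_oracle(0.7)
  pop <- new_population(cfg, oracle)
  n_fixed_total <- 0L
  for (gen in 1:150) {
    prev_next <- pop$next_id
    pop <- wf_step(pop, cfg, oracle)
    expect_gte(pop$next_id, prev_next)
    fx <- detect_and_purge_fixations(pop, oracle)
    pop <- fx$population
    n_fixed_total <- n_fixed_total + length(fx$fixed_ids)
    for (s in pop$sets) {
      expect_equal(anyDuplicated(s), 0L)
      expect_false(any(s %in% oracle$fixed))
      expect_true(all(s < pop$next_id))
    }
    # per-individual distance to the fixed-background ancestor is the set size
    expect_equal(individual_mutation_counts(pop), lengths(pop$sets))
  }
  expect_gt(n_fixed_total, 0L)   # fixations do occur at these rates
})

test_that("a fully lethal generation raises an extinction error carrying the
           generation index", {
  world <- manual_landscape(c(TRUE, FALSE))   # L = 1, only genotype 0 viable
  cfg <- sim_config(N = 5, L = 1, mu = 1, r = 0, p = 0.5)
  pop <- new_population(cfg, world, start = 0L)
  set.seed(20)
  pop <- wf_step(pop, cfg, world)   # every offspring mutates to the lethal
  expect_true(all(pop$fitness == 0))
  err <- tryCatch(wf_step(pop, cfg, world), error = identity)
  expect_s3_class(err, "extinction_error")
  expect_equal(err$generation, 1L)
})

test_that("obligate Poisson mode recombines every offspring and admits r > 1", {
  set.seed(22)
  cfg <- sim_config(N = 40, U = 0.1, r = 2.5, p = 1,
                    crossover = "obligate_poisson")
  oracle <- ism_oracle(1)
  pop <- step_n(new_population(cfg, oracle), cfg, oracle, 5)
  expect_equal(pop$tally$recombination_events, 40L)
  expect_error(sim_config(N = 10, U = 0.1, r = 1.5, p = 1), "'r'")
})
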