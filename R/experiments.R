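#' Stationary averages of population observables
#'
#' Evolves a population for `burn_in` generations, then records observables
#' every `interval` generations `n_samples` times and returns batch-means
#' estimates with standard errors.  Rate observables (`r_dis`, `r_fix`,
#' `v_rec`) are accumulated every generation of the sampling window, the
#' state observables (`d_pw`, `Y`, `S`, `m`, `w_bar`) at the sampling times
#' only.
#'
#' Defaults are scaled for desk-size runs: the coalescent autocorrelation
#' time is of order `N` generations, so `burn_in = 20 * N` and
#' `interval = N / 10` give effectively decorrelated samples; standard errors
#' are reported so that shorter runs remain honest.
#'
#' @param cfg A [sim_config()].  When `cfg$seed` is set the global RNG is
#'   seeded at the start of the run.
#' @param observables Character vector from `d_pw` (pairwise mean Hamming
#'   distance), `Y` (distinct viable genotypes), `S` (segregating mutations),
#'   `m` (mutational robustness, finite sites only), `w_bar` (mean fitness),
#'   `r_dis` (discovery rate), `r_fix` (fixation rate, infinite sites only),
#'   `v_rec` (viable recombination fraction).  `NULL` selects all defined for
#'   the representation.
#' @param burn_in Generations discarded before sampling.
#' @param n_samples Number of recorded samples.
#' @param interval Generations between samples.
#' @param world Optional pre-built `percolation_landscape` or [ism_oracle()];
#'   generated from `cfg` when `NULL`.
#' @param n_batches Number of batches for batch-means standard errors.
#' @return A data frame with one row per observable and columns `observable`,
#'   `mean`, `se`, `n_samples`, `burn_in`, `interval`.  The realized world and
#'   final population are attached as attributes `world` and `population`.
#' @export
run_stationary <- function(cfg, observables = NULL,
                           burn_in = 20L * cfg$N, n_samples = 1000L,
                           interval = max(1L, round(cfg$N / 10)),
                           world = NULL, n_batches = 20L) {
  stopifnot(burn_in >= 1L, interval >= 1L, n_samples >= 2L)
  finite <- cfg$representation == "finite"
  all_obs <- if (finite) c("d_pw", "Y", "S", "m", "w_bar", "r_dis", "v_rec")
             else c("d_pw", "Y", "S", "w_bar", "r_dis", "r_fix", "v_rec")
  if (is.null(observables)) observables <- all_obs
  bad <- setdiff(observables, all_obs)
  if (length(bad)) {
    stop("observables not defined for this representation: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(world)) {
    world <- if (finite) {
      generate_connected_landscape(cfg$L, cfg$p, cfg$w0)
    } else {
      ism_oracle(cfg$p)
    }
  }
  pop <- new_population(cfg, world)
  tracker <- discovery_tracker(world)
  update_discovery(tracker, pop, 0L)

  state_obs <- intersect(observables, c("d_pw", "Y", "S", "m", "w_bar"))
  n_gens_sampled <- n_samples * interval
  total <- burn_in + n_gens_sampled
  state_mat <- matrix(NA_real_, n_samples, length(state_obs),
                      dimnames = list(NULL, state_obs))
  dis <- fix <- rec <- vrec <- numeric(n_gens_sampled)
  row <- 0L
  for (gen in seq_len(total)) {
    pop <- wf_step(pop, cfg, world)
    nfix <- 0L
    if (!finite) {
      fx <- detect_and_purge_fixations(pop, world, tracker)
      pop <- fx$population
      nfix <- length(fx$fixed_ids)
    }
    ndis <- update_discovery(tracker, pop, gen)
    if (gen > burn_in) {
      t <- gen - burn_in
      dis[t] <- ndis
      fix[t] <- nfix
      rec[t] <- pop$tally$recombination_events
      vrec[t] <- pop$tally$viable_recombinants
      if (t %% interval == 0L) {
        row <- row + 1L
        for (ob in state_obs) {
          state_mat[row, ob] <- switch(ob,
            d_pw = pairwise_mean_hamming(pop),
            Y = distinct_viable_genotypes(pop),
            S = segregating_mutations(pop),
            m = mutational_robustness(pop, world),
            w_bar = mean_fitness(pop))
        }
      }
    }
  }

  est <- lapply(observables, function(ob) {
    if (ob %in% state_obs) {
      batch_means(state_mat[, ob], n_batches)
    } else if (ob == "r_dis") {
      batch_means(dis, n_batches)
    } else if (ob == "r_fix") {
      batch_means(fix, n_batches)
    } else {                                  # v_rec: ratio of sums
      batch_ratio(vrec, rec, n_batches)
    }
  })
  out <- data.frame(observable = observables,
                    mean = vapply(est, `[[`, numeric(1), "mean"),
                    se = vapply(est, `[[`, numeric(1), "se"),
                    n_samples = n_samples, burn_in = burn_in,
                    interval = interval, row.names = NULL)
  attr(out, "config") <- cfg
  attr(out, "world") <- world
  attr(out, "population") <- pop
  out
}

# batch-means estimate: overall mean plus SE from nb contiguous batch means
batch_means <- function(x, nb = 20L) {
  n <- length(x)
  nb <- max(2L, min(nb, n %/% 2L))
  bs <- n %/% nb
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  list(mean = mean(x), se = stats::sd(bm) / sqrt(nb))
}

# ratio-of-sums estimate with batch-level ratios for the SE
batch_ratio <- function(num, den, nb = 20L) {
  if (sum(den) == 0) return(list(mean = NA_real_, se = NA_real_))
  n <- length(num)
  nb <- max(2L, min(nb, n %/% 2L))
  bs <- n %/% nb
  bn <- colSums(matrix(num[seq_len(nb * bs)], nrow = bs))
  bd <- colSums(matrix(den[seq_len(nb * bs)], nrow = bs))
  keep <- bd > 0
  ratios <- bn[keep] / bd[keep]
  se <- if (sum(keep) >= 2L) stats::sd(ratios) / sqrt(sum(keep)) else NA_real_
  list(mean = sum(num) / sum(den), se = se)
}

#' Evolve until every viable genotype has been discovered
#'
#' Starts from a monomorphic population on a uniformly random viable genotype
#' (counted as discovered at generation 0) and evolves until all viable
#' genotypes of the landscape have been present in at least one individual in
#' at least one generation, or `max_generations` is reached.  In the
#' trapped regime (strong recombination on a holey landscape) the discovery
#' time diverges; such runs are reported censored rather than infinite.
#'
#' @param cfg A finite-sites [sim_config()].
#' @param landscape A connected `percolation_landscape`.
#' @param max_generations Censoring horizon.
#' @return A list with `t_fdis` (generations until full discovery, or the
#'   horizon), `n_mut` (cumulative mutation events), and `censored`.
#' @export
run_full_discovery <- function(cfg, landscape, max_generations = 1e6) {
  stopifnot(cfg$representation == "finite",
            inherits(landscape, "percolation_landscape"))
  if (!viable_network_connected(landscape$viability, landscape$L)) {
    stop("landscape is not connected; full discovery would be unreachable")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- new_population(cfg, landscape)
  tracker <- discovery_tracker(landscape)
  update_discovery(tracker, pop, 0L)
  n_mut <- 0
  if (full_discovery(tracker)) {
    return(list(t_fdis = 0L, n_mut = 0, censored = FALSE))
  }
  for (gen in seq_len(max_generations)) {
    pop <- wf_step(pop, cfg, landscape)
    n_mut <- n_mut + pop$tally$mutation_events
    update_discovery(tracker, pop, gen)
    if (full_discovery(tracker)) {
      return(list(t_fdis = gen, n_mut = n_mut, censored = FALSE))
    }
  }
  list(t_fdis = max_generations, n_mut = n_mut, censored = TRUE)
}

#' Time until a random escape variant is discovered
#'
#' A scenario in which one predetermined viable genotype (an escape variant,
#' drawn uniformly among viable genotypes other than the start) must be found
#' by at least one individual.  Also reports the mutational robustness of the
#' escape variant and of the start genotype, for stratified summaries.
#'
#' @inheritParams run_full_discovery
#' @param start,escape Optional genotype indices; drawn uniformly among
#'   viable genotypes when `NULL`.
#' @return A list with `t_escape` (`>= 1`; the start is never the escape
#'   variant), `m_escape`, `m_start`, the genotype indices `start` and
#'   `escape`, their Hamming distance `distance` (a strong nuisance
#'   covariate for stratified summaries), and `censored`.
#' @export
run_escape <- function(cfg, landscape, max_generations = 1e6,
                       start = NULL, escape = NULL) {
  stopifnot(cfg$representation == "finite",
            inherits(landscape, "percolation_landscape"))
  if (!viable_network_connected(landscape$viability, landscape$L)) {
    stop("landscape is not connected; the escape variant could be unreachable")
  }
  viable_idx <- which(landscape$viability) - 1L
  if (length(viable_idx) < 2L) {
    stop("escape runs require at least two viable genotypes")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(start)) start <- viable_idx[sample.int(length(viable_idx), 1L)]
  if (is.null(escape)) {
    others <- setdiff(viable_idx, start)
    escape <- others[sample.int(length(others), 1L)]
  }
  stopifnot(start != escape)
  pop <- new_population(cfg, landscape, start = start)
  base <- list(m_escape = robustness_indices(landscape, escape),
               m_start = robustness_indices(landscape, start),
               start = start, escape = escape,
               distance = popcount(bitwXor(start, escape), landscape$L))
  for (gen in seq_len(max_generations)) {
    pop <- wf_step(pop, cfg, landscape)
    if (any(pop$geno == escape)) {
      return(c(list(t_escape = gen), base, list(censored = FALSE)))
    }
  }
  c(list(t_escape = max_generations), base, list(censored = TRUE))
}

#' Ensemble time evolution of observables
#'
#' Runs `n_realizations` independent realizations -- each with a fresh
#' landscape (or oracle) and a fresh monomorphic population on a random
#' viable genotype -- for `generations` generations, recording the requested
#' observables every generation, and returns per-generation ensemble means
#' and standard deviations.
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the master stream from which
#'   per-realization seeds are drawn.
#' @param observables Subset of `d_pw`, `Y`, `S`, `m` (finite sites), `w_bar`.
#' @param generations Number of generations per realization.
#' @param n_realizations Ensemble size (`>= 2`).
#' @return A named list of data frames, one per observable, with columns
#'   `generation` (0-based), `mean`, `sd`, `n_realizations`.
#' @export
run_time_series <- function(cfg, observables = c("d_pw", "Y", "S", "w_bar"),
                            generations = 100L, n_realizations = 10L) {
  stopifnot(generations >= 1L, n_realizations >= 2L)
  finite <- cfg$representation == "finite"
  allowed <- if (finite) c("d_pw", "Y", "S", "m", "w_bar")
             else c("d_pw", "Y", "S", "w_bar")
  stopifnot(all(observables %in% allowed))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_realizations)
  traj <- lapply(observables, function(ob) {
    matrix(NA_real_, n_realizations, generations + 1L)
  })
  names(traj) <- observables
  for (rl in seq_len(n_realizations)) {
    set.seed(seeds[rl])
    world <- if (finite) generate_connected_landscape(cfg$L, cfg$p, cfg$w0)
             else ism_oracle(cfg$p)
    pop <- new_population(cfg, world)
    record <- function(gen) {
      for (ob in observables) {
        traj[[ob]][rl, gen + 1L] <<- switch(ob,
          d_pw = pairwise_mean_hamming(pop),
          Y = distinct_viable_genotypes(pop),
          S = segregating_mutations(pop),
          m = mutational_robustness(pop, world),
          w_bar = mean_fitness(pop))
      }
    }
    record(0L)
    for (gen in seq_len(generations)) {
      pop <- wf_step(pop, cfg, world)
      if (!finite) {
        pop <- detect_and_purge_fixations(pop, world)$population
      }
      record(gen)
    }
  }
  lapply(traj, function(m) {
    data.frame(generation = 0:generations,
               mean = colMeans(m),
               sd = apply(m, 2, stats::sd),
               n_realizations = n_realizations)
  })
}

#' Define a parameter sweep
#'
#' @param axes Named list of parameter values to cross (names must be
#'   [sim_config()] arguments, e.g. `list(r = c(0, 0.5, 1))`).
#' @param base Named list of the fixed [sim_config()] arguments.
#' @param replicates Independent replicates (landscape and seed) per grid
#'   point.
#' @param master_seed Master seed; per-point seeds are derived from it by a
#'   documented counter scheme, making sweeps resumable and byte-identical
#'   when rerun.
#' @param burn_in,n_samples,interval Passed to [run_stationary()]; `NULL`
#'   uses its defaults.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(axes, base, replicates = 1L, master_seed = 1L,
                       burn_in = NULL, n_samples = 1000L, interval = NULL) {
  stopifnot(is.list(axes), length(names(axes)) == length(axes),
            is.list(base), replicates >= 1L)
  structure(list(axes = axes, base = base, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed), burn_in = burn_in,
                 n_samples = n_samples, interval = interval),
            class = "sweep_grid")
}

# per-point seed: a fixed linear-congruential mix of master seed, grid point
# index and replicate index, reduced mod 2^31 - 2 (kept in exact double range)
derive_seed <- function(master_seed, point, replicate) {
  m <- 2147483646
  s <- ((master_seed %% 65536) * 65537 + point * 10007 + replicate * 101) %% m
  as.integer(s + 1)
}

#' Run a parameter sweep of stationary estimates
#'
#' One [run_stationary()] call per grid point and replicate; per-point
#' failures (e.g. extinction) are recorded in the output row and the sweep
#' continues.
#'
#' @param grid A [sweep_grid()].
#' @param observables Passed to [run_stationary()].
#' @return A data frame with one row per grid point and replicate: the axis
#'   values, `replicate`, `seed`, one `<observable>_mean` / `<observable>_se`
#'   column pair per observable, and `ok` / `error` status columns.
#' @export
run_sweep <- function(grid, observables = NULL) {
  stopifnot(inherits(grid, "sweep_grid"))
  points <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(points))) {
    for (k in seq_len(grid$replicates)) {
      seed <- derive_seed(grid$master_seed, i, k)
      args <- utils::modifyList(grid$base, as.list(points[i, , drop = FALSE]))
      args$seed <- seed
      res <- tryCatch({
        cfg <- do.call(sim_config, args)
        st_args <- list(cfg = cfg, observables = observables,
                        n_samples = grid$n_samples)
        if (!is.null(grid$burn_in)) st_args$burn_in <- grid$burn_in
        if (!is.null(grid$interval)) st_args$interval <- grid$interval
        do.call(run_stationary, st_args)
      }, error = function(e) e)
      row <- cbind(points[i, , drop = FALSE],
                   data.frame(replicate = k, seed = seed))
      if (inherits(res, "error")) {
        row$ok <- FALSE
        row$error <- conditionMessage(res)
      } else {
        for (j in seq_len(nrow(res))) {
          row[[paste0(res$observable[j], "_mean")]] <- res$mean[j]
          row[[paste0(res$observable[j], "_se")]] <- res$se[j]
        }
        row$ok <- TRUE
        row$error <- NA_character_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (n in setdiff(nm, names(r))) r[[n]] <- NA
    r[nm]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  out
}
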