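test_that("stationary estimates are exact in degenerate regimes", {
  cfg <- sim_config(N = 20, U = 0, r = 0, p = 1, seed = 101)
  res <- run_stationary(cfg, c("d_pw", "Y", "S"), burn_in = 10,
                        n_samples = 20, interval = 1)
  expect_equal(res$mean[res$observable == "d_pw"], 0)
  expect_equal(res$mean[res$observable == "Y"], 1)
  expect_equal(res$mean[res$observable == "S"], 0)
})

test_that("full discovery on a single-viable-genotype landscape is immediate
           and disconnected landscapes are refused", {
  world <- manual_landscape(c(TRUE, rep(FALSE, 7)))
  cfg <- sim_config(N = 10, L = 3, mu = 0.01, r = 0, p = 0.1, seed = 5)
  out <- run_full_discovery(cfg, world)
  expect_equal(out$t_fdis, 0L)
  expect_equal(out$n_mut, 0)
  expect_false(out$censored)
  disc <- manual_landscape(c(TRUE, rep(FALSE, 6), TRUE))
  expect_error(run_full_discovery(cfg, disc), "not connected")
})

test_that("slow discovery runs are censored at the horizon, not reported as
           finished", {
  set.seed(42)
  world <- generate_connected_landscape(6, 0.7)
  cfg <- sim_config(N = 20, L = 6, mu = 1e-5, r = 0, p = 0.7, seed = 9)
  out <- run_full_discovery(cfg, world, max_generations = 50)
  expect_true(out$censored)
  expect_equal(out$t_fdis, 50)
})

test_that("mutation events until full discovery track t_fdis * N * L * mu
           when double mutations are rare", {
  set.seed(43)
  tot_mut <- 0
  tot_pred <- 0
  for (i in 1:3) {
    world <- generate_connected_landscape(6, 0.7)
    cfg <- sim_config(N = 50, L = 6, mu = 2e-3, r = 0, p = 0.7)
    out <- run_full_discovery(cfg, world, max_generations = 5e4)
    expect_false(out$censored)
    tot_mut <- tot_mut + out$n_mut
    tot_pred <- tot_pred + mutation_events_relation(out$t_fdis, 50, 6, 2e-3)
  }
  expect_lt(abs(tot_mut / tot_pred - 1), 0.05)
})

test_that("escape runs report first-hit times of at least one generation and
           the robustness of both endpoints", {
  set.seed(44)
  world <- generate_connected_landscape(5, 0.8)
  viable <- which(world$viability) - 1L
  start <- viable[1]
  nb <- neutralnets:::neighbor_indices(start, 5)
  escape <- nb[world$viability[nb + 1L]][1]    # a viable direct neighbor
  cfg <- sim_config(N = 50, L = 5, mu = 0.05, r = 0, p = 0.8)
  out <- run_escape(cfg, world, max_generations = 1e4,
                    start = start, escape = escape)
  expect_gte(out$t_escape, 1L)
  expect_false(out$censored)
  expect_equal(out$m_start, genotype_robustness(world,
                                                finite_genotype(start, 5)))
  expect_equal(out$m_escape, genotype_robustness(world,
                                                 finite_genotype(escape, 5)))
})

test_that("ensemble time series start monomorphic and stay constant without
           mutation", {
  cfg <- sim_config(N = 15, L = 4, mu = 0, r = 0.5, p = 0.8, seed = 77)
  ts <- run_time_series(cfg, c("Y", "d_pw"), generations = 10,
                        n_realizations = 4)
  expect_equal(ts$Y$mean, rep(1, 11))
  expect_equal(ts$Y$sd, rep(0, 11))
  expect_equal(ts$d_pw$mean, rep(0, 11))
  cfg2 <- sim_config(N = 15, L = 4, mu = 0.05, r = 0, p = 0.8, seed = 78)
  ts2 <- run_time_series(cfg2, "Y", generations = 5, n_realizations = 3)
  expect_equal(ts2$Y$mean[1], 1)   # monomorphic start in every realization
  expect_equal(ts2$Y$sd[1], 0)
})

test_that("sweeps derive per-point seeds deterministically and reproduce
           single runs exactly", {
  grid <- sweep_grid(axes = list(r = c(0, 1)),
                     base = list(N = 15, U = 0.1, p = 1),
                     replicates = 2, master_seed = 7,
                     burn_in = 30, n_samples = 40, interval = 2)
  sw1 <- run_sweep(grid, c("d_pw", "S"))
  sw2 <- run_sweep(grid, c("d_pw", "S"))
  expect_identical(sw1, sw2)                       # byte-identical rerun
  expect_equal(nrow(sw1), 4L)
  expect_true(all(sw1$ok))
  # a 1x1 grid is exactly one run_stationary call with the derived seed
  g11 <- sweep_grid(axes = list(r = 0.5),
                    base = list(N = 15, U = 0.1, p = 1),
                    replicates = 1, master_seed = 3,
                    burn_in = 30, n_samples = 40, interval = 2)
  sw <- run_sweep(g11, "d_pw")
  cfg <- sim_config(N = 15, U = 0.1, p = 1, r = 0.5,
                    seed = neutralnets:::derive_seed(3, 1, 1))
  ref <- run_stationary(cfg, "d_pw", burn_in = 30, n_samples = 40,
                        interval = 2)
  expect_equal(sw$d_pw_mean, ref$mean[1])
  expect_equal(sw$d_pw_se, ref$se[1])
})

test_that("per-point failures are recorded in-row and the sweep continues", {
  # r = 1.5 under uniform crossover is an invalid grid point; the sweep must
  # record the config error in-row and still run the valid point
  grid <- sweep_grid(axes = list(r = c(1.5, 0)),
                     base = list(N = 5, L = 3, mu = 0.01, p = 1),
                     replicates = 1, master_seed = 1,
                     burn_in = 5, n_samples = 5, interval = 1)
  sw <- run_sweep(grid, "Y")
  expect_equal(sw$ok, c(FALSE, TRUE))
  expect_match(sw$error[1], "'r'")
  expect_false(is.na(sw$Y_mean[2]))
})
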