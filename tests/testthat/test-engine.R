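test_that("configurations are validated and founders are monomorphic", {
  expect_error(sim_config(N = 0), "N")
  expect_error(sim_config(u_init = 0), "positive")
  expect_error(sim_config(epsilon = -1), "epsilon")

  cfg <- quick_config(N = 120, u_init = 1, r_init = 4)
  pop <- init_population(cfg)
  expect_length(pop$u, 120L)
  expect_true(all(pop$u == 1) && all(pop$r == 4))
  expect_true(all(pop$age == 0L) && all(is.na(pop$t_since)))
  expect_equal(length(unique(pop$id)), 120L)
})

test_that("all founders update on the first step (newborn rule)", {
  cfg <- quick_config(N = 200, t_max = 1, epsilon = 0, seed = 6)
  res <- run_simulation(cfg)
  tr <- res$trajectory
  expect_equal(tr$update_freq[1], 1)
  expect_equal(tr$mean_mismatch[1], 0)  # epsilon = 0: perfect updates
})

test_that("identical configurations reproduce bit-identical results", {
  cfg <- quick_config(N = 80, t_max = 150, epsilon = 0.2, seed = 99)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
  cfg2 <- quick_config(N = 80, t_max = 150, epsilon = 0.2, seed = 100)
  expect_false(identical(run_simulation(cfg)$final_snapshot,
                         run_simulation(cfg2)$final_snapshot))
})

test_that("a frozen, perfectly tracked world leaves genotypes untouched", {
  cfg <- sim_config(N = 60, t_max = 120, env = ar1_env(0.999),
                    epsilon = 0, mutation_sd = 0, u_init = 50,
                    r_init = 4, seed = 2)
  res <- run_simulation(cfg)
  expect_equal(res$status, "completed")
  expect_true(all(res$final_snapshot$u == 50))
  expect_true(all(res$final_snapshot$r == 4))
  expect_equal(max(res$trajectory$mean_mismatch), 0)
})

test_that("runs terminate with extinct status when recruitment fails", {
  # kappa = 1 + constant updating: all clutch weights are zero, the
  # population can only shrink, and extinction is a status, not an error
  cfg <- sim_config(N = 40, t_max = 3000, env = ar1_env(0.5), epsilon = 0,
                    life = life_params(kappa = 1, alpha0 = 0.3),
                    u_init = 1e6, r_init = 4, seed = 12)
  expect_warning(res <- run_simulation(cfg), "extinct")
  expect_equal(res$status, "extinct")
  expect_true(is.finite(res$extinct_at))
  expect_null(res$final_snapshot)
  expect_true(nrow(res$trajectory) < 3000 / cfg$record_every + 1)
})

test_that("trajectories are strictly ordered and populations at capacity", {
  cfg <- quick_config(N = 150, t_max = 400, seed = 8, epsilon = 0.2)
  res <- run_simulation(cfg)
  tr <- res$trajectory
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$size == 150))
  expect_equal(tr$t[nrow(tr)], 400)
  expect_equal(nrow(res$final_snapshot), 150L)
  # terminal panel: 10 steps, one row per individual alive in each
  expect_equal(sort(unique(res$last_panel$t)), 391:400)
  expect_equal(nrow(res$last_panel), 10L * 150L)
})

test_that("grid runs are labeled, independent and reproducible", {
  cfg <- quick_config(N = 50, t_max = 100, seed = 5)
  g <- run_grid(cfg, u_init = c(0.1, 1), r_init = c(1, 4), seeds = 1:2)
  lab <- attr(g, "grid")
  expect_equal(nrow(lab), 8L)
  expect_length(g, 8L)
  expect_equal(anyDuplicated(lab$seed), 0L)
  expect_true(all(lab$status == "completed"))

  # a single-cell grid is one plain run under the derived seed
  g1 <- run_grid(cfg, u_init = 1, r_init = 4, seeds = 1L)
  cfg1 <- cfg; cfg1$u_init <- 1; cfg1$r_init <- 4
  cfg1$seed <- attr(g1, "grid")$seed[1]
  expect_identical(g1[[1]], run_simulation(cfg1))

  # distinct replicate seeds give distinct trajectories
  expect_false(identical(g[[1]]$final_snapshot, g[[5]]$final_snapshot))
})

test_that("reproductive effort evolves faster than the updating schedule", {
  # displaced starts: u far below, r far above their evolved values; the
  # time for the population mean to cover half the distance to its final
  # value should be shorter for r than for u in most replicates
  wins <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(N = 250, t_max = 2500, env = ar1_env(0.5),
                      epsilon = 0, u_init = 0.01, r_init = 7,
                      seed = 400 + s, record_every = 10)
    tr <- run_simulation(cfg)$trajectory
    half_time <- function(v, init) {
      final <- mean(v[(length(v) - 9):length(v)])
      idx <- which(abs(v - final) <= 0.5 * abs(init - final))
      if (length(idx)) tr$t[idx[1]] else Inf
    }
    t_r <- half_time(tr$mean_r, 7)
    t_u <- half_time(log(tr$mean_u), log(0.01))
    if (t_r < t_u) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
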