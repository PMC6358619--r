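test_that("clutch size combines effort, mismatch and the updating cost", {
  expect_equal(clutch_size(9, 0, updated = 0, kappa = 0.4), 9)
  expect_equal(clutch_size(9, 0, updated = 1, kappa = 0.4), 5.4)
  expect_equal(clutch_size(12, 1, updated = 0), 10 * exp(-1))
  # mortality-only variant drops the mismatch factor but keeps the cost
  expect_equal(clutch_size(9, 1, 1, kappa = 0.4,
                           mismatch_mode = "mortality_only"), 5.4)
  # variants reduce to the main model when mismatch is zero
  for (mode in c("mortality_only", "fecundity_only", "none"))
    expect_equal(clutch_size(6, 0, 1, mismatch_mode = mode),
                 clutch_size(6, 0, 1, mismatch_mode = "both"))
  # non-increasing in mismatch and in the update indicator
  m <- seq(0, 3, by = 0.25)
  expect_true(all(diff(clutch_size(5, m, 0)) <= 0))
  expect_true(all(clutch_size(5, m, 1) <= clutch_size(5, m, 0)))
})

test_that("mortality adds baseline, mismatch and the effort cost, clamped", {
  expect_equal(mortality_prob(0, 0), 0.05)
  expect_equal(mortality_prob(0.2, 3, rho = 0.01, alpha0 = 0.05), 0.34)
  expect_equal(mortality_prob(2, 10, rho = 0.05), 1)
  expect_equal(mortality_prob(1.5, 0, rho = 0, alpha0 = 0), 1)
  # fecundity-only variant drops the mismatch term
  expect_equal(mortality_prob(2, 3, rho = 0.01, mismatch_mode = "fecundity_only"),
               0.05 + 0.01 * 9)
  for (mode in c("mortality_only", "fecundity_only", "none"))
    expect_equal(mortality_prob(0, 4, mismatch_mode = mode),
                 mortality_prob(0, 4, mismatch_mode = "both"))
  # non-decreasing in mismatch and in effort
  expect_true(all(diff(mortality_prob(seq(0, 2, 0.1), 3)) >= 0))
  expect_true(all(diff(mortality_prob(0.1, seq(0, 12, 0.5))) >= 0))
})

test_that("life-history parameters are validated", {
  expect_error(life_params(kappa = 1.2), "kappa")
  expect_error(life_params(rho = -0.1), "rho")
  expect_error(life_params(mismatch_mode = "sometimes"), "arg")
  expect_equal(life_params(mismatch_mode = "none")$mismatch_mode, "none")
})

test_that("recruits are drawn in proportion to expected clutch size", {
  pop <- homog_population(2, u = 1, r = 4, x = 0)
  pop$u <- c(1, 2); pop$r <- c(4, 5)

  expect_length(draw_recruits(pop, c(3, 1), 0)$u, 0L)
  expect_length(draw_recruits(pop, c(0, 0), 5)$u, 0L)
  expect_error(draw_recruits(pop, c(3, 1), -1), ">= 0")

  set.seed(13)
  n <- 1e5
  rec <- draw_recruits(pop, c(3, 1), n, mutation_sd = 0)
  frac1 <- mean(rec$parent == 1L)
  expect_lt(abs(frac1 - 0.75), 2.576 * sqrt(0.75 * 0.25 / n))
  # sd = 0 recruits carry their parent's genotype exactly
  expect_equal(rec$u, pop$u[rec$parent])
  expect_equal(rec$r, pop$r[rec$parent])
})

test_that("step ordering lets this step's dead parents still reproduce", {
  # certain death for everyone, positive clutch: full one-step turnover
  pop <- homog_population(50, u = 1, r = 6, x = 0)
  life <- life_params(rho = 1, alpha0 = 0.05)  # rho r^2 >> 1
  set.seed(5)
  st <- step_population(pop, E_t = 0, life, epsilon = 0)
  expect_true(all(st$outcome$died))
  expect_equal(length(st$pop$u), 50L)
  expect_true(all(st$pop$age == 0L))
  expect_true(all(is.na(st$pop$t_since)))
})

test_that("zero total clutch weight leaves vacancies unfilled", {
  # kappa = 1 makes every updater's clutch exactly zero; huge u makes
  # everyone update, so the population can only shrink
  pop <- homog_population(200, u = 1e6, r = 4, x = 0)
  life <- life_params(kappa = 1, rho = 0, alpha0 = 0.3)
  set.seed(9)
  st <- step_population(pop, E_t = 0, life, epsilon = 0)
  expect_true(all(st$outcome$updated))
  expect_equal(st$outcome$clutch, rep(0, 200))
  expect_equal(st$outcome$n_recruits, 0L)
  expect_equal(length(st$pop$u), 200L - sum(st$outcome$died))
  expect_gt(sum(st$outcome$died), 0L)
})

test_that("population stays at capacity whenever clutch weight is positive", {
  cfg <- quick_config(N = 80, t_max = 60, seed = 4)
  pop <- init_population(cfg)
  E <- simulate_env(cfg$env, cfg$t_max, seed = 2)
  set.seed(3)
  for (t in 1:60) {
    st <- step_population(pop, E[t + 1], cfg$life, epsilon = 0)
    expect_lte(length(st$pop$u), 80L)
    if (sum(st$outcome$clutch) > 0) expect_equal(length(st$pop$u), 80L)
    expect_lte(st$outcome$n_recruits, sum(st$outcome$died))
    pop <- st$pop
  }
})

test_that("per-step death fractions match the analytic probability", {
  pop <- homog_population(1e5, u = 1, r = 3, x = 0.2)
  life <- life_params()  # both: 0.05 + 0.2 + 0.01 * 9 = 0.34
  set.seed(17)
  # huge u would force updates; u tiny and t_since = 1 keeps phenotypes put
  pop$u <- rep(1e-9, 1e5)
  st <- step_population(pop, E_t = 0, life, epsilon = 0)
  pr <- mortality_prob(0.2, 3)
  expect_lt(abs(mean(st$outcome$died) - pr),
            2.576 * sqrt(pr * (1 - pr) / 1e5))
})
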