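# Deterministic sub-seed derivation: a counter-based modular hash keeps
# every derived seed a valid 32-bit integer and makes grid cells
# statistically independent yet reproducible from one master seed.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
                as.double(stream) * 1299721 + 12345) %% 2147483647)
}

#' Simulation configuration
#'
#' Full parameterization of one simulation run. Defaults are the baseline
#' study conditions: 2000 individuals for 50,000 steps.
#'
#' @param N population capacity (constant population size); default 2000.
#' @param t_max number of time steps; default 50000.
#' @param env an [`env_params`][ar1_env] object; default `ar1_env(0.5)`.
#' @param epsilon updating-error standard deviation, `>= 0`; default 0.
#' @param life a [life_params()] object.
#' @param mutation_sd log-scale mutation standard deviation; default 0.01.
#' @param u_init founding value of the updating-schedule gene, positive.
#' @param r_init founding value of the reproductive-effort gene, positive.
#' @param seed master RNG seed for the run. Environment and demography use
#'   separate sub-streams derived from it, so the environmental realization
#'   is held fixed across life-history variants sharing a seed.
#' @param record_every trajectory-recording stride in steps; default 50.
#' @param record_last number of final steps for which full individual-level
#'   records are kept (the senescence-regression window); default 10.
#' @param env_init initial-state rule passed to [simulate_env()].
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(N = 100, t_max = 500, u_init = 1, r_init = 4, seed = 1)
#' @export
sim_config <- function(N = 2000, t_max = 50000, env = ar1_env(0.5),
                       epsilon = 0, life = life_params(),
                       mutation_sd = 0.01, u_init = 1, r_init = 4,
                       seed = 1, record_every = 50, record_last = 10,
                       env_init = "stationary") {
  stopifnot(inherits(env, "env_params"), inherits(life, "life_params"))
  N <- as.integer(N); t_max <- as.integer(t_max)
  if (is.na(N) || N < 1L) stop("'N' must be >= 1", call. = FALSE)
  if (is.na(t_max) || t_max < 1L) stop("'t_max' must be >= 1", call. = FALSE)
  if (u_init <= 0 || r_init <= 0)
    stop("'u_init' and 'r_init' must be positive", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  if (mutation_sd < 0) stop("'mutation_sd' must be >= 0", call. = FALSE)
  structure(list(N = N, t_max = t_max, env = env, epsilon = epsilon,
                 life = life, mutation_sd = mutation_sd,
                 u_init = u_init, r_init = r_init,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 record_last = as.integer(record_last),
                 env_init = env_init),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: N = %d, t_max = %d, seed = %d\n",
              x$N, x$t_max, x$seed))
  print(x$env)
  print(x$life)
  cat(sprintf("  epsilon = %g, mutation sd = %g, u_init = %g, r_init = %g\n",
              x$epsilon, x$mutation_sd, x$u_init, x$r_init))
  invisible(x)
}

#' Found a population from a configuration
#'
#' Creates `N` monomorphic founders with `u = u_init`, `r = r_init`,
#' age 0 and the newborn waiting-time sentinel, so every founder updates
#' its phenotype with probability 1 on the first step.
#'
#' @param config a [sim_config()] object.
#' @return A `population` object.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  new_population(u = rep.int(config$u_init, N),
                 r = rep.int(config$r_init, N),
                 x = rep.int(0, N),
                 t_since = rep.int(NA_integer_, N),
                 age = rep.int(0L, N),
                 id = as.numeric(seq_len(N)),
                 capacity = N, next_id = N + 1)
}

#' Run one simulation
#'
#' The main entry point: generates the environmental series, founds the
#' population, iterates [step_population()] for `t_max` steps, and records
#' (i) a population-mean trajectory every `record_every` steps, (ii) full
#' individual-level panels for the final `record_last` steps, and (iii) the
#' standing population at `t_max`. A run whose population hits size zero
#' terminates early with status `"extinct"` rather than an error.
#'
#' @param config a [sim_config()] object.
#' @param progress print progress lines every `progress` recorded steps
#'   (0 = silent, the default).
#' @return An object of class `plastisim` with components:
#' \describe{
#'   \item{status}{`"completed"` or `"extinct"`.}
#'   \item{final_snapshot}{data frame of all individuals at `t_max` (`id`,
#'     `age`, `u`, `r`, `x`, `m`); `NULL` for extinct runs.}
#'   \item{trajectory}{data frame of recorded population means (`t`,
#'     `mean_u`, `mean_r`, `mean_mismatch`, `mean_age`, `update_freq`,
#'     `size`).}
#'   \item{last_panel}{pooled individual-step records for the final
#'     `record_last` steps (`t`, `id`, `age`, `u`, `r`, `x`, `m`,
#'     `updated`, `clutch`, `died`).}
#'   \item{extinct_at}{step of extinction, or `NA`.}
#'   \item{config}{the configuration, echoed.}
#' }
#' @examples
#' res <- run_simulation(sim_config(N = 100, t_max = 300, u_init = 1,
#'                                  r_init = 4, seed = 7))
#' summary(res)
#' @export
run_simulation <- function(config, progress = 0) {
  stopifnot(inherits(config, "sim_config"))
  env <- simulate_env(config$env, config$t_max,
                      seed = derive_seed(config$seed, 1L),
                      init = config$env_init)
  set.seed(derive_seed(config$seed, 2L))
  pop <- init_population(config)

  t_max <- config$t_max
  steps <- seq_len(t_max)
  rec_idx <- unique(c(steps[steps %% config$record_every == 0L], t_max))
  traj <- matrix(NA_real_, nrow = length(rec_idx), ncol = 7L,
                 dimnames = list(NULL, c("t", "mean_u", "mean_r",
                                         "mean_mismatch", "mean_age",
                                         "update_freq", "size")))
  ri <- 1L
  panel_from <- t_max - config$record_last + 1L
  panel <- vector("list", config$record_last)
  status <- "completed"
  extinct_at <- NA_integer_

  for (t in seq_len(t_max)) {
    pre <- pop  # parents, for panel records
    st <- step_population(pop, env[t + 1L], config$life,
                          epsilon = config$epsilon,
                          mutation_sd = config$mutation_sd)
    pop <- st$pop
    out <- st$outcome

    if (t >= panel_from) {
      panel[[t - panel_from + 1L]] <- data.frame(
        t = t, id = pre$id, age = out$age, u = pre$u, r = pre$r,
        x = pre$x, m = out$m, updated = as.integer(out$updated),
        clutch = out$clutch, died = as.integer(out$died))
    }
    if (ri <= length(rec_idx) && t == rec_idx[ri]) {
      traj[ri, ] <- c(t, mean(pre$u), mean(pre$r), mean(out$m),
                      mean(out$age), mean(out$updated), length(pop$u))
      if (progress > 0 && ri %% progress == 0L)
        message(sprintf("t = %d: size %d, mean u %.4g, r %.4g, m %.4g",
                        t, length(pop$u), mean(pre$u), mean(pre$r),
                        mean(out$m)))
      ri <- ri + 1L
    }
    if (length(pop$u) == 0L) {
      status <- "extinct"
      extinct_at <- t
      warning(sprintf("population went extinct at step %d", t),
              call. = FALSE)
      break
    }
  }

  final_snapshot <- NULL
  if (status == "completed") {
    final_snapshot <- as.data.frame(pop)
    final_snapshot$m <- abs(final_snapshot$x - env[t_max + 1L])
    final_snapshot$t_since_update <- NULL
  }
  panel <- panel[!vapply(panel, is.null, logical(1L))]
  last_panel <- if (length(panel)) do.call(rbind, panel) else NULL
  traj <- as.data.frame(traj[!is.na(traj[, "t"]), , drop = FALSE])

  structure(list(status = status, final_snapshot = final_snapshot,
                 trajectory = traj, last_panel = last_panel,
                 extinct_at = extinct_at, config = config),
            class = "plastisim")
}

#' @export
print.plastisim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Plasticity/life-history simulation (N = %d, t_max = %d, seed = %d)\n",
              cfg$N, cfg$t_max, cfg$seed))
  cat(sprintf("  status: %s%s\n", x$status,
              if (x$status == "extinct")
                sprintf(" (at step %d)", x$extinct_at) else ""))
  if (!is.null(x$final_snapshot)) {
    fs <- x$final_snapshot
    cat(sprintf("  at t_max: mean u %.4g, mean r %.4g, mean mismatch %.4g, mean age %.3g\n",
                mean(fs$u), mean(fs$r), mean(fs$m), mean(fs$age)))
  }
  invisible(x)
}

#' Plot a simulation trajectory
#'
#' Four base-graphics panels of the recorded population means against
#' time: updating gene (log scale), reproductive-effort gene, mismatch,
#' and mean age.
#'
#' @param x a `plastisim` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.plastisim <- function(x, ...) {
  tr <- x$trajectory
  if (nrow(tr) == 0L) {
    warning("no recorded trajectory to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$t, tr$mean_u, type = "l", log = "y", xlab = "time step",
                 ylab = "mean u", main = "updating schedule", ...)
  graphics::plot(tr$t, tr$mean_r, type = "l", xlab = "time step",
                 ylab = "mean r", main = "reproductive effort", ...)
  graphics::plot(tr$t, tr$mean_mismatch, type = "l", xlab = "time step",
                 ylab = "mean mismatch", main = "phenotypic mismatch", ...)
  graphics::plot(tr$t, tr$mean_age, type = "l", xlab = "time step",
                 ylab = "mean age", main = "population age", ...)
  invisible(x)
}

#' Run a grid of simulations over initial genotype values
#'
#' One environmental scenario, many starts: runs every combination of
#' `u_init`, `r_init` and replicate seed under a shared base configuration.
#' The defaults are the canonical initialization grids
#' `u_init = 10^seq(-2, 1, by = 0.5)` (i.e. 0.01, 0.0316, ..., 10) and
#' `r_init = c(1, 4, 7)`, giving 21 runs per seed. Per-run seeds are
#' derived from `config$seed` by a counter scheme, so cells are independent
#' but the whole grid is reproducible.
#'
#' @param config the base [sim_config()]; its `u_init`, `r_init`, `seed`
#'   are overridden cell by cell.
#' @param u_init vector of founding updating-gene values.
#' @param r_init vector of founding effort-gene values.
#' @param seeds vector of replicate labels; each is hashed with the master
#'   seed to give the run seed.
#' @param progress if `TRUE`, print one line per completed run.
#' @return An object of class `plastisim_grid`: a list of `plastisim`
#'   results with a `grid` data frame attribute (`u_init`, `r_init`,
#'   `replicate`, `seed`, `status`).
#' @export
run_grid <- function(config, u_init = 10^seq(-2, 1, by = 0.5),
                     r_init = c(1, 4, 7), seeds = 1L, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            length(u_init) > 0L, length(r_init) > 0L, length(seeds) > 0L)
  cells <- expand.grid(u_init = u_init, r_init = r_init,
                       replicate = seeds, KEEP.OUT.ATTRS = FALSE)
  runs <- vector("list", nrow(cells))
  run_seed <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    run_seed[i] <- derive_seed(config$seed,
                               1000L * cells$replicate[i] + i)
    cfg <- config
    cfg$u_init <- cells$u_init[i]
    cfg$r_init <- cells$r_init[i]
    cfg$seed <- run_seed[i]
    runs[[i]] <- suppressWarnings(run_simulation(cfg))
    if (progress)
      message(sprintf("run %d/%d (u0 %.4g, r0 %g, rep %d): %s",
                      i, nrow(cells), cells$u_init[i], cells$r_init[i],
                      cells$replicate[i], runs[[i]]$status))
  }
  cells$seed <- run_seed
  cells$status <- vapply(runs, function(r) r$status, character(1L))
  structure(runs, grid = cells, class = "plastisim_grid")
}

#' @export
print.plastisim_grid <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Simulation grid: %d runs (%d completed, %d extinct)\n",
              nrow(g), sum(g$status == "completed"),
              sum(g$status == "extinct")))
  invisible(x)
}
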