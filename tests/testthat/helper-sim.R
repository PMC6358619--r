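# Small-scale configuration builder shared across tests. Defaults keep a
# single run well under a second while preserving the model structure.
quick_config <- function(N = 100, t_max = 200, p = 0.5, epsilon = 0,
                         u_init = 1, r_init = 4, seed = 1, ...) {
  sim_config(N = N, t_max = t_max, env = ar1_env(p), epsilon = epsilon,
             u_init = u_init, r_init = r_init, seed = seed, ...)
}

# A homogeneous population of n identical individuals with defined state,
# bypassing the founder (newborn-sentinel) path.
homog_population <- function(n, u = 1, r = 4, x = 0, t_since = 1L, age = 1L) {
  pop <- init_population(sim_config(N = n, t_max = 1, u_init = u,
                                    r_init = r, seed = 1))
  pop$x <- rep.int(x, n)
  pop$t_since <- rep.int(as.integer(t_since), n)
  pop$age <- rep.int(as.integer(age), n)
  pop
}

# Minimal completed-run object for summary arithmetic tests.
fake_result <- function(snapshot, panel = NULL, config = quick_config()) {
  structure(list(status = "completed", final_snapshot = snapshot,
                 trajectory = data.frame(), last_panel = panel,
                 extinct_at = NA_integer_, config = config),
            class = "plastisim")
}
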