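#' Life-history parameters
#'
#' Collects the demographic cost parameters and the model-variant switch.
#'
#' @param kappa fecundity cost of performing an update, in `[0, 1]`;
#'   default 0.4 (robustness variants use 0.2 and 0.6).
#' @param rho coefficient of the mortality cost of reproduction, `>= 0`;
#'   mortality rises by `rho * r^2`. Default 0.01 (robustness variant 0.05).
#' @param alpha0 baseline per-step mortality probability; default 0.05.
#' @param r_cap upper bound on realized clutch size; default 10.
#' @param mismatch_mode which vital rates mismatch affects: `"both"` (the
#'   main model), `"mortality_only"` (mismatch dropped from fecundity),
#'   `"fecundity_only"` (mismatch dropped from mortality), or `"none"`
#'   (mismatch affects nothing; a diagnostic mode that, with `kappa = 0`,
#'   makes the updating gene selectively neutral).
#' @return An object of class `life_params`.
#' @export
life_params <- function(kappa = 0.4, rho = 0.01, alpha0 = 0.05, r_cap = 10,
                        mismatch_mode = c("both", "mortality_only",
                                          "fecundity_only", "none")) {
  mismatch_mode <- match.arg(mismatch_mode)
  if (kappa < 0 || kappa > 1) stop("'kappa' must be in [0, 1]", call. = FALSE)
  if (rho < 0) stop("'rho' must be >= 0", call. = FALSE)
  if (alpha0 < 0 || alpha0 > 1)
    stop("'alpha0' must be in [0, 1]", call. = FALSE)
  if (r_cap <= 0) stop("'r_cap' must be positive", call. = FALSE)
  structure(list(kappa = kappa, rho = rho, alpha0 = alpha0, r_cap = r_cap,
                 mismatch_mode = mismatch_mode),
            class = "life_params")
}

#' @export
print.life_params <- function(x, ...) {
  cat(sprintf(paste0("Life history: kappa = %g, rho = %g, alpha0 = %g, ",
                     "r_cap = %g, mismatch_mode = %s\n"),
              x$kappa, x$rho, x$alpha0, x$r_cap, x$mismatch_mode))
  invisible(x)
}

#' Expected clutch size
#'
#' Combines reproductive effort, mismatch and the updating cost:
#' \deqn{c = \min(r_{cap}, r)\; e^{-m^2}\,(1 - \kappa U),}
#' where `U = 1` for individuals that updated this step. Under
#' `mismatch_mode = "mortality_only"` or `"none"` the \eqn{e^{-m^2}} factor
#' is dropped (the updating cost is retained).
#'
#' @param r reproductive-effort gene value(s), positive.
#' @param m mismatch value(s), `>= 0`.
#' @param updated 0/1 (or logical) update indicator(s).
#' @param kappa updating fecundity cost in `[0, 1]`.
#' @param r_cap clutch-size cap.
#' @param mismatch_mode model variant, see [life_params()].
#' @return Nonnegative expected clutch sizes.
#' @examples
#' clutch_size(9, 0, updated = 1, kappa = 0.4)   # 9 * 0.6 = 5.4
#' clutch_size(12, 1, updated = 0)               # capped: 10 * exp(-1)
#' @export
clutch_size <- function(r, m, updated, kappa = 0.4, r_cap = 10,
                        mismatch_mode = "both") {
  stopifnot(all(is.finite(r)), all(is.finite(m)), all(m >= 0))
  cl <- pmin(r_cap, r) * (1 - kappa * as.numeric(updated))
  if (mismatch_mode %in% c("both", "fecundity_only"))
    cl <- cl * exp(-m^2)
  cl
}

#' Per-step mortality probability
#'
#' Baseline mortality plus the mismatch penalty plus the cost of
#' reproduction:
#' \deqn{P[\mathrm{death}] = \alpha_0 + m + \rho r^2,}
#' clamped to `[0, 1]` (the linear form can exceed 1 for large mismatch or
#' effort). Under `mismatch_mode = "fecundity_only"` or `"none"` the `m`
#' term is dropped.
#'
#' @param m mismatch value(s), `>= 0`.
#' @param r reproductive-effort gene value(s).
#' @param rho reproduction-cost coefficient.
#' @param alpha0 baseline mortality probability.
#' @param mismatch_mode model variant, see [life_params()].
#' @return Death probabilities in `[0, 1]`.
#' @examples
#' mortality_prob(0.2, 3, rho = 0.01)   # 0.05 + 0.2 + 0.09 = 0.34
#' @export
mortality_prob <- function(m, r, rho = 0.01, alpha0 = 0.05,
                           mismatch_mode = "both") {
  stopifnot(all(is.finite(m)), all(m >= 0), all(is.finite(r)))
  pr <- alpha0 + rho * r^2
  if (mismatch_mode %in% c("both", "mortality_only"))
    pr <- pr + m
  pmin(1, pmax(0, pr))
}

#' Draw recruits to fill vacancies
#'
#' Dead adults leave vacancies that are filled by newborn recruits. Parents
#' are drawn with replacement from all individuals alive at reproduction
#' time (including those that die this step: reproduction precedes
#' mortality), with probability proportional to expected clutch size. Each
#' recruit inherits its parent's genotype through [mutate_genotype()],
#' starts at age 0 with the newborn waiting-time sentinel, and carries the
#' parent's phenotype until its first (certain) update. If every clutch
#' size is zero no recruits are produced and the vacancies stay open.
#'
#' @param pop a `population` (the parents, pre-mortality).
#' @param clutch expected clutch sizes aligned with `pop`.
#' @param vacancies number of open slots, `>= 0`.
#' @param mutation_sd log-scale mutation standard deviation.
#' @return A list with parallel vectors `u`, `r`, `x`, `parent` (parent
#'   index) of length `min(vacancies, ...)`; zero-length if no clutch
#'   weight is positive or `vacancies == 0`.
#' @export
draw_recruits <- function(pop, clutch, vacancies, mutation_sd = 0.01) {
  if (vacancies < 0) stop("'vacancies' must be >= 0", call. = FALSE)
  n <- length(pop$u)
  if (vacancies == 0L || n == 0L || sum(clutch) <= 0)
    return(list(u = numeric(0), r = numeric(0), x = numeric(0),
                parent = integer(0)))
  parent <- sample.int(n, size = vacancies, replace = TRUE, prob = clutch)
  g <- mutate_genotype(pop$u[parent], pop$r[parent], sd = mutation_sd)
  list(u = g$u, r = g$r, x = pop$x[parent], parent = parent)
}

#' Advance a population by one time step
#'
#' Executes the full per-step schedule against the current environmental
#' optimum `E_t`, in this order:
#' \enumerate{
#'   \item ages and update waiting times increment (newborns keep their
#'     sentinel until they update);
#'   \item each individual updates its phenotype with probability
#'     [update_probability()]; updaters get [update_phenotype()] draws and
#'     their waiting time resets to 0;
#'   \item mismatch is recomputed against `E_t` for everyone;
#'   \item expected clutch sizes are computed ([clutch_size()]);
#'   \item each individual dies with probability [mortality_prob()];
#'   \item recruits fill the vacancies ([draw_recruits()]), drawn from all
#'     individuals alive at reproduction time — including this step's dead.
#' }
#' The population returns to capacity whenever total clutch weight is
#' positive; if all clutch sizes are zero it shrinks, possibly to
#' extinction.
#'
#' @param pop a `population` object.
#' @param E_t environmental optimum for this step.
#' @param life a [life_params()] object.
#' @param epsilon updating-error standard deviation.
#' @param mutation_sd log-scale mutation standard deviation.
#' @return A list with `pop` (the post-step population) and `outcome`, a
#'   list of per-parent vectors (`m`, `clutch`, `updated`, `died`) plus the
#'   recruit count, all aligned with the pre-step population order.
#' @export
step_population <- function(pop, E_t, life, epsilon = 0, mutation_sd = 0.01) {
  n <- length(pop$u)
  if (n == 0L)
    return(list(pop = pop,
                outcome = list(m = numeric(0), clutch = numeric(0),
                               updated = logical(0), died = logical(0),
                               n_recruits = 0L)))

  # (1) ages and waiting times
  age <- pop$age + 1L
  t_since <- pop$t_since + 1L  # NA (newborn) stays NA

  # (2) stochastic updating
  pr_up <- 1 - exp(-pop$u * t_since)
  pr_up[is.na(t_since)] <- 1
  updated <- stats::runif(n) < pr_up
  x <- pop$x
  x[updated] <- update_phenotype(sum(updated), E_t, epsilon)
  t_since[updated] <- 0L

  # (3) mismatch
  m <- abs(x - E_t)

  # (4) fecundity
  cl <- clutch_size(pop$r, m, updated, kappa = life$kappa,
                    r_cap = life$r_cap, mismatch_mode = life$mismatch_mode)

  # (5) mortality
  pr_death <- mortality_prob(m, pop$r, rho = life$rho, alpha0 = life$alpha0,
                             mismatch_mode = life$mismatch_mode)
  died <- stats::runif(n) < pr_death

  # (6) recruitment from the pre-mortality parent pool
  keep <- !died
  vacancies <- pop$capacity - sum(keep)
  rec <- draw_recruits(pop, cl, vacancies, mutation_sd = mutation_sd)
  k <- length(rec$u)

  new_pop <- new_population(
    u = c(pop$u[keep], rec$u),
    r = c(pop$r[keep], rec$r),
    x = c(x[keep], rec$x),
    t_since = c(t_since[keep], rep.int(NA_integer_, k)),
    age = c(age[keep], rep.int(0L, k)),
    id = c(pop$id[keep], if (k > 0L) pop$next_id + seq_len(k) - 1 else numeric(0)),
    capacity = pop$capacity,
    next_id = pop$next_id + k)

  list(pop = new_pop,
       outcome = list(m = m, clutch = cl, updated = updated, died = died,
                      age = age, n_recruits = k))
}
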