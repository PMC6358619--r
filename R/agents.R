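#' Probability of a phenotype update
#'
#' Per-step probability that an individual refreshes its phenotype, as a
#' function of its updating-schedule gene `u` and the time `t_since_update`
#' since its last update:
#' \deqn{P[\mathrm{update}] = 1 - e^{-u\,T_u}.}
#' High `u` means the probability rises steeply with waiting time, i.e.
#' frequent updating. Newborns, whose waiting time is undefined, update
#' with probability 1 regardless of `u`; they are encoded by
#' `t_since_update = NA`.
#'
#' @param u updating-schedule gene, positive; recycled against
#'   `t_since_update`.
#' @param t_since_update integer steps since the last update (`>= 0`), or
#'   `NA` for a newborn.
#' @return Update probabilities in `[0, 1]`, with 1 for every newborn.
#' @examples
#' update_probability(1, 1)        # 1 - exp(-1)
#' update_probability(0.1, NA)     # newborn: 1
#' @export
update_probability <- function(u, t_since_update) {
  if (any(!is.finite(u)) || any(u <= 0))
    stop("'u' must be positive and finite", call. = FALSE)
  if (any(t_since_update < 0, na.rm = TRUE))
    stop("'t_since_update' must be >= 0 (or NA for newborns)", call. = FALSE)
  pr <- 1 - exp(-u * t_since_update)
  pr[is.na(t_since_update)] <- 1
  pr
}

#' Phenotypic mismatch
#'
#' Absolute difference between a phenotype and the current environmental
#' optimum, \eqn{m = |x - E_t|}. Mismatch reduces fecundity (through
#' \eqn{e^{-m^2}}) and raises mortality (additively), depending on the
#' model variant in force.
#'
#' @param x phenotype(s).
#' @param E_t environmental optimum.
#' @return Nonnegative mismatch values.
#' @export
mismatch <- function(x, E_t) {
  stopifnot(all(is.finite(x)), all(is.finite(E_t)))
  abs(x - E_t)
}

#' Draw post-update phenotypes
#'
#' The phenotype after an update is the current optimum plus updating
#' error, \eqn{E_t + N(0, \epsilon)} with `epsilon` a standard deviation.
#' With `epsilon = 0` an update removes the mismatch exactly; large
#' `epsilon` can increase it.
#'
#' @param n number of updating individuals.
#' @param E_t current environmental optimum.
#' @param epsilon updating-error standard deviation, `>= 0`.
#' @return `n` post-update phenotypes.
#' @export
update_phenotype <- function(n, E_t, epsilon) {
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (epsilon == 0) rep.int(E_t, n) else stats::rnorm(n, E_t, epsilon)
}

#' Inherit a genotype with multiplicative mutation
#'
#' Offspring inherit the parent's two gene values with independent
#' log-scale perturbations:
#' \deqn{u' = e^{\log u + \mu_u}, \quad r' = e^{\log r + \mu_r}, \quad
#'       \mu \sim N(0, \mathrm{sd}^2).}
#' The exponential map keeps both genes strictly positive, and mutation is
#' driftless on the log scale. The mutation scale is a standard deviation
#' (default 0.01).
#'
#' @param u,r parental gene values, positive; equal lengths.
#' @param sd mutation standard deviation on the log scale, `>= 0`.
#' @return A list with components `u` and `r`, the mutated offspring values.
#' @examples
#' mutate_genotype(1, 4, sd = 0)    # identical to the parent
#' @export
mutate_genotype <- function(u, r, sd = 0.01) {
  if (any(u <= 0) || any(r <= 0))
    stop("parental gene values must be positive", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  n <- length(u)
  if (sd == 0) return(list(u = u, r = r))
  list(u = u * exp(stats::rnorm(n, 0, sd)),
       r = r * exp(stats::rnorm(n, 0, sd)))
}

# Internal population container: parallel vectors, one slot per individual.
# t_since is NA for newborns (the undefined-waiting-time sentinel); x of a
# newborn is its parent's phenotype, irrelevant in practice because newborns
# update with probability 1 before first reproducing.
new_population <- function(u, r, x, t_since, age, id, capacity, next_id) {
  structure(list(u = u, r = r, x = x, t_since = t_since,
                 age = age, id = id,
                 capacity = as.integer(capacity),
                 next_id = as.numeric(next_id)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  n <- length(x$u)
  cat(sprintf("Population: %d individuals (capacity %d)\n", n, x$capacity))
  if (n > 0L)
    cat(sprintf("  mean u %.4g, mean r %.4g, mean age %.3g\n",
                mean(x$u), mean(x$r), mean(x$age)))
  invisible(x)
}

#' Flatten a population to individual records
#'
#' @param x a `population` object.
#' @param ... unused.
#' @return A data frame with one row per individual: `id`, `age`, `u`,
#'   `r`, `x` (phenotype) and `t_since_update` (`NA` for newborns).
#' @export
as.data.frame.population <- function(x, ...) {
  data.frame(id = x$id, age = x$age, u = x$u, r = x$r, x = x$x,
             t_since_update = x$t_since)
}
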