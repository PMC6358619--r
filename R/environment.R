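#' Autoregressive environment parameters
#'
#' Construct the parameter object for the fluctuating environmental optimum.
#' The baseline process is AR(1),
#' \deqn{E_t = p E_{t-1} + (1 - p)\,\zeta_t, \qquad \zeta_t \sim N(0, 1),}
#' where `p` weights the previous state against a fresh standard-normal draw
#' and therefore sets the autocorrelation of the environment. Note that `p`
#' also scales the stationary variance, \eqn{(1-p)/(1+p)}: a "stable"
#' environment (high `p`) fluctuates both more slowly and less widely.
#'
#' @param p autocorrelation weight, in `[0, 1)`.
#' @param innovation_sd standard deviation of the innovation \eqn{\zeta};
#'   the default 1 is the standard-normal draw of the baseline model.
#' @return An object of class `c("ar1_env", "env_params")`.
#' @seealso [arma21_env()], [arma21_from_target()], [simulate_env()]
#' @examples
#' ar1_env(0.9)
#' @export
ar1_env <- function(p, innovation_sd = 1) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0 || p >= 1)
    stop("'p' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(innovation_sd) || innovation_sd <= 0)
    stop("'innovation_sd' must be a positive number", call. = FALSE)
  structure(list(kind = "AR1", p = p, innovation_sd = innovation_sd),
            class = c("ar1_env", "env_params"))
}

#' ARMA(2,1) environment parameters
#'
#' Construct an ARMA(2,1) environmental process
#' \deqn{E_t = a_1 E_{t-1} + a_2 E_{t-2} + \eta_t + b_1 \eta_{t-1},}
#' with \eqn{\eta_t \sim N(0, \sigma^2)}. Unlike the AR(1) baseline, this
#' family can vary the lag-1 autocorrelation while holding the total
#' stationary variance fixed (see [arma21_from_target()]), which is what
#' makes it useful as a robustness check on the autocorrelation effect.
#'
#' @param ar numeric vector of length 2, the AR coefficients `(a1, a2)`.
#' @param ma single MA coefficient `b1`.
#' @param innovation_sd positive innovation standard deviation.
#' @return An object of class `c("arma21_env", "env_params")`.
#' @export
arma21_env <- function(ar, ma, innovation_sd = 1) {
  stopifnot(is.numeric(ar), length(ar) == 2L, all(is.finite(ar)),
            is.numeric(ma), length(ma) == 1L, is.finite(ma))
  if (!is.numeric(innovation_sd) || innovation_sd <= 0)
    stop("'innovation_sd' must be a positive number", call. = FALSE)
  # stationarity: roots of 1 - a1 z - a2 z^2 outside the unit circle;
  # invertibility: root of 1 + b1 z outside the unit circle
  if (any(Mod(polyroot(c(1, -ar))) <= 1))
    stop("AR coefficients do not define a stationary process ",
         "(characteristic root inside or on the unit circle)", call. = FALSE)
  if (ma != 0 && any(Mod(polyroot(c(1, ma))) <= 1))
    stop("MA coefficient does not define an invertible process", call. = FALSE)
  structure(list(kind = "ARMA21", ar = as.numeric(ar), ma = as.numeric(ma),
                 innovation_sd = innovation_sd),
            class = c("arma21_env", "env_params"))
}

#' @export
print.env_params <- function(x, ...) {
  if (x$kind == "AR1") {
    mom <- stationary_moments_ar1(x$p)
    cat(sprintf("AR(1) environment: p = %g, innovation sd = %g\n",
                x$p, x$innovation_sd))
    cat(sprintf("  stationary variance %.4g, lag-1 autocorrelation %.4g\n",
                mom$variance * x$innovation_sd^2, mom$lag1_autocorr))
  } else {
    mom <- arma_stationary_moments(x)
    cat(sprintf("ARMA(2,1) environment: ar = (%g, %g), ma = %g, innovation sd = %g\n",
                x$ar[1], x$ar[2], x$ma, x$innovation_sd))
    cat(sprintf("  stationary variance %.4g, lag-1 autocorrelation %.4g\n",
                mom$variance, mom$lag1_autocorr))
  }
  invisible(x)
}

#' One AR(1) environment step
#'
#' The elementary recursion `p * E_prev + (1 - p) * noise`. Exposed mainly
#' for testing and didactic use; [simulate_env()] generates whole series.
#'
#' @param E_prev previous environmental state.
#' @param p autocorrelation weight in `[0, 1)`.
#' @param noise the innovation draw (standard normal in the baseline model).
#' @return The next environmental state.
#' @export
step_ar1 <- function(E_prev, p, noise) {
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)", call. = FALSE)
  stopifnot(all(is.finite(E_prev)), all(is.finite(noise)))
  p * E_prev + (1 - p) * noise
}

#' Stationary moments of the AR(1) environment
#'
#' Closed-form stationary variance and lag-1 autocorrelation of
#' \eqn{E_t = p E_{t-1} + (1-p)\zeta_t} with unit-variance innovations:
#' variance \eqn{(1-p)^2/(1-p^2) = (1-p)/(1+p)} and autocorrelation `p`.
#'
#' @param p autocorrelation weight in `[0, 1)`.
#' @return A list with components `variance` and `lag1_autocorr`.
#' @export
stationary_moments_ar1 <- function(p) {
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)", call. = FALSE)
  list(variance = (1 - p) / (1 + p), lag1_autocorr = p)
}

#' Stationary moments of an environment process
#'
#' Theoretical stationary variance and lag-1 autocorrelation for either
#' environment family. For the ARMA(2,1) process the variance is computed
#' from the infinite-MA (psi-weight) representation and the autocorrelation
#' from [stats::ARMAacf()].
#'
#' @param params an [`env_params`][ar1_env] object.
#' @param n_psi number of psi weights used for the ARMA variance; the
#'   truncation error is geometric and negligible at the default.
#' @return A list with components `variance` and `lag1_autocorr`.
#' @export
arma_stationary_moments <- function(params, n_psi = 2000L) {
  stopifnot(inherits(params, "env_params"))
  if (params$kind == "AR1") {
    mom <- stationary_moments_ar1(params$p)
    return(list(variance = mom$variance * params$innovation_sd^2,
                lag1_autocorr = mom$lag1_autocorr))
  }
  psi <- stats::ARMAtoMA(ar = params$ar, ma = params$ma, lag.max = n_psi)
  list(variance = params$innovation_sd^2 * (1 + sum(psi^2)),
       lag1_autocorr = unname(
         stats::ARMAacf(ar = params$ar, ma = params$ma, lag.max = 1L)[2L]))
}

#' Construct an ARMA(2,1) environment with target autocorrelation and variance
#'
#' Solves for ARMA(2,1) parameters whose stationary process has a given
#' lag-1 autocorrelation and total variance. The "shape" coefficients
#' `ar2` and `ma1` are held fixed, `ar1` is found by root-finding on the
#' theoretical lag-1 autocorrelation, and the innovation standard deviation
#' is rescaled to hit the target variance. Because the variance is set
#' independently of the autocorrelation, sweeps over the autocorrelation
#' leave the total environmental variance unchanged — the property the
#' AR(1) baseline lacks.
#'
#' @param lag1_autocorr target lag-1 autocorrelation, in `(-1, 1)`.
#' @param variance target stationary variance, positive. Default 1.
#' @param ar2 fixed second AR coefficient. Default 0.
#' @param ma1 fixed MA coefficient. Default 0.3.
#' @return An [`arma21_env`] object meeting the targets.
#' @examples
#' e <- arma21_from_target(0.6, variance = 1)
#' arma_stationary_moments(e)
#' @export
arma21_from_target <- function(lag1_autocorr, variance = 1,
                               ar2 = 0, ma1 = 0.3) {
  stopifnot(is.numeric(lag1_autocorr), length(lag1_autocorr) == 1L)
  if (abs(lag1_autocorr) >= 1)
    stop("'lag1_autocorr' must lie in (-1, 1)", call. = FALSE)
  if (!is.numeric(variance) || variance <= 0)
    stop("'variance' must be positive", call. = FALSE)
  if (abs(ar2) >= 1)
    stop("'ar2' must lie in (-1, 1) for stationarity", call. = FALSE)

  # stationarity triangle for AR(2): a1 + a2 < 1, a2 - a1 < 1, |a2| < 1
  lo <- (ar2 - 1) * 0.999
  hi <- (1 - ar2) * 0.999
  acf1 <- function(a1)
    unname(stats::ARMAacf(ar = c(a1, ar2), ma = ma1, lag.max = 1L)[2L]) -
      lag1_autocorr
  f_lo <- acf1(lo); f_hi <- acf1(hi)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0)
    stop(sprintf(paste0("target lag-1 autocorrelation %.3f is infeasible with ",
                        "ar2 = %.3f, ma1 = %.3f (attainable range [%.3f, %.3f])"),
                 lag1_autocorr, ar2, ma1,
                 min(f_lo, f_hi) + lag1_autocorr,
                 max(f_lo, f_hi) + lag1_autocorr), call. = FALSE)
  a1 <- stats::uniroot(acf1, c(lo, hi), tol = 1e-12)$root

  unit <- arma21_env(ar = c(a1, ar2), ma = ma1, innovation_sd = 1)
  var_unit <- arma_stationary_moments(unit)$variance
  arma21_env(ar = c(a1, ar2), ma = ma1,
             innovation_sd = sqrt(variance / var_unit))
}

#' Simulate an environmental optimum series
#'
#' Generates the scalar environmental optimum \eqn{E_t} for
#' `t = 0, ..., t_max`. AR(1) series are generated by the linear recursion
#' (via [stats::filter()]); ARMA(2,1) series by [stats::arima.sim()], whose
#' burn-in starts the process near its stationary distribution.
#'
#' @param params an [`env_params`][ar1_env] object.
#' @param t_max number of time steps (series length is `t_max + 1`).
#' @param seed optional integer seed; identical seeds give identical series.
#' @param init initial-state rule for the AR(1) process: `"stationary"`
#'   draws \eqn{E_0} from the stationary distribution (the default, so the
#'   series needs no burn-in), `"zero"` starts at \eqn{E_0 = 0}.
#' @return An object of class `env_series`: a numeric vector of length
#'   `t_max + 1` with the generating `params` and `seed` attached as
#'   attributes.
#' @examples
#' E <- simulate_env(ar1_env(0.9), t_max = 1000, seed = 1)
#' var(E); acf(E, plot = FALSE, lag.max = 1)
#' @export
simulate_env <- function(params, t_max, seed = NULL,
                         init = c("stationary", "zero")) {
  stopifnot(inherits(params, "env_params"))
  init <- match.arg(init)
  t_max <- as.integer(t_max)
  if (is.na(t_max) || t_max < 1L)
    stop("'t_max' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (params$kind == "AR1") {
    p <- params$p
    e0 <- if (init == "stationary")
      stats::rnorm(1L, 0, sqrt(stationary_moments_ar1(p)$variance) *
                     params$innovation_sd)
    else 0
    z <- stats::rnorm(t_max, 0, params$innovation_sd)
    vals <- c(e0, as.numeric(
      stats::filter((1 - p) * z, p, method = "recursive", init = e0)))
  } else {
    vals <- as.numeric(stats::arima.sim(
      model = list(ar = params$ar, ma = params$ma), n = t_max + 1L,
      sd = params$innovation_sd))
  }
  structure(vals, params = params, seed = seed, class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("Environment series: %d steps (t = 0..%d)\n",
              length(x) - 1L, length(x) - 1L))
  print(attr(x, "params"))
  cat(sprintf("  sample mean %.4g, sample variance %.4g\n",
              mean(x), stats::var(as.numeric(x))))
  invisible(x)
}

#' @export
as.data.frame.env_series <- function(x, ...) {
  data.frame(t = seq_along(x) - 1L, E = as.numeric(x))
}
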