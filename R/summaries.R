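#' Senescence slope: mismatch regressed on age
#'
#' Ordinary least-squares slope of individual mismatch on individual age
#' over the pooled individual-step records of the final steps of a run
#' (each individual contributes one row per step it was present in, with
#' no within-individual clustering correction). A positive slope means
#' older individuals are more mismatched to the current environment — the
#' model's operational form of senescence; frequent updating keeps it near
#' zero. Pooling several terminal steps averages out the particular
#' environmental state at any one step.
#'
#' @param panel a data frame with numeric columns `m` and `age` (the
#'   `last_panel` component of a [run_simulation()] result).
#' @return The OLS slope, or `NA` if all ages are identical (the slope is
#'   then undefined).
#' @examples
#' mismatch_age_slope(data.frame(age = 1:5, m = 0.1 * (1:5)))  # exactly 0.1
#' @export
mismatch_age_slope <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("m", "age") %in% names(panel)))
  if (nrow(panel) < 2L) return(NA_real_)
  va <- stats::var(panel$age)
  if (!is.finite(va) || va == 0) return(NA_real_)
  stats::cov(panel$m, panel$age) / va
}

#' Summarize a run
#'
#' End-of-run statistics: cross-sectional means of age (the lifespan
#' proxy), the two gene values and mismatch over the standing population
#' at `t_max`, plus the mismatch~age senescence slope from the terminal
#' panel. Extinct runs yield a row with `status = "extinct"` and missing
#' statistics.
#'
#' @param object a `plastisim` object.
#' @param ... unused.
#' @return A one-row data frame of class `plastisim_summary` with columns
#'   `status`, `p` (or `NA` for ARMA environments), `epsilon`, `kappa`,
#'   `rho`, `mismatch_mode`, `u_init`, `r_init`, `seed`, `mean_age`,
#'   `mean_u`, `mean_r`, `mean_mismatch`, `mismatch_age_slope`.
#' @export
summary.plastisim <- function(object, ...) {
  cfg <- object$config
  base <- data.frame(
    status = object$status,
    p = if (cfg$env$kind == "AR1") cfg$env$p else NA_real_,
    epsilon = cfg$epsilon,
    kappa = cfg$life$kappa,
    rho = cfg$life$rho,
    mismatch_mode = cfg$life$mismatch_mode,
    u_init = cfg$u_init, r_init = cfg$r_init, seed = cfg$seed,
    stringsAsFactors = FALSE)
  if (object$status != "completed" || is.null(object$final_snapshot)) {
    base$mean_age <- NA_real_; base$mean_u <- NA_real_
    base$mean_r <- NA_real_; base$mean_mismatch <- NA_real_
    base$mismatch_age_slope <- NA_real_
  } else {
    fs <- object$final_snapshot
    base$mean_age <- mean(fs$age)
    base$mean_u <- mean(fs$u)
    base$mean_r <- mean(fs$r)
    base$mean_mismatch <- mean(fs$m)
    base$mismatch_age_slope <- mismatch_age_slope(object$last_panel)
  }
  class(base) <- c("plastisim_summary", "data.frame")
  base
}

#' @export
print.plastisim_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy table of run summaries
#'
#' Stacks [summary.plastisim()] rows for a collection of runs into one
#' tidy table, one row per run — the unit of the cross-population
#' comparisons ([pattern_tests()]).
#'
#' @param runs a `plastisim_grid`, a list of `plastisim` objects, or a
#'   single `plastisim`.
#' @return A data frame, one row per run.
#' @export
sweep_table <- function(runs) {
  if (inherits(runs, "plastisim")) runs <- list(runs)
  stopifnot(is.list(runs), length(runs) > 0L)
  out <- do.call(rbind, lapply(runs, summary))
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Cross-population pattern tests
#'
#' The comparative statistics computed across evolved populations:
#' \itemize{
#'   \item Spearman rank correlation between evolved mean reproductive
#'     effort and evolved mean updating gene (expected negative: plastic
#'     populations evolve low effort);
#'   \item Spearman rank correlation between mean age at the end of the
#'     run and evolved mean updating gene (expected positive: long
#'     lifespan only at high plasticity);
#'   \item a 1-D k-means clustering of `log10(mean_u)` into high /
#'     (intermediate /) low updating-frequency groups;
#'   \item a per-scenario alternative-equilibria flag: within one
#'     environmental scenario (`p`, `epsilon`), evolved `mean_u` clusters
#'     separated by more than one order of magnitude indicate
#'     initial-condition-dependent equilibria.
#' }
#'
#' @param table a [sweep_table()] data frame.
#' @param k number of updating-frequency clusters (2 or 3); default 3.
#' @param min_runs minimum completed runs required; fewer returns a
#'   diagnostics-only report.
#' @return An object of class `plastisim_patterns`: a list with
#'   `spearman_r_u`, `spearman_age_u`, `clusters` (per-run assignment and
#'   centers on the log10 scale), `alternative_equilibria` (per-scenario
#'   flags) and `n_completed`.
#' @export
pattern_tests <- function(table, k = 3L, min_runs = 5L) {
  stopifnot(is.data.frame(table))
  k <- as.integer(k)
  if (k < 2L || k > 3L) stop("'k' must be 2 or 3", call. = FALSE)
  tab <- table[table$status == "completed" & is.finite(table$mean_u), ,
               drop = FALSE]
  res <- list(n_completed = nrow(tab), n_total = nrow(table))
  if (nrow(tab) < min_runs) {
    res$message <- sprintf("only %d completed runs (need >= %d)",
                           nrow(tab), min_runs)
    class(res) <- "plastisim_patterns"
    return(res)
  }
  res$spearman_r_u <- stats::cor(tab$mean_r, tab$mean_u, method = "spearman")
  res$spearman_age_u <- stats::cor(tab$mean_age, tab$mean_u,
                                   method = "spearman")

  lu <- log10(tab$mean_u)
  km <- stats::kmeans(lu, centers = min(k, length(unique(lu))), nstart = 10L)
  ord <- order(km$centers)  # relabel so cluster 1 = lowest updating
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  res$clusters <- list(assignment = relabel[km$cluster],
                       centers_log10_u = sort(as.numeric(km$centers)))

  scen <- interaction(tab$p, tab$epsilon, drop = TRUE)
  flags <- vapply(split(lu, scen), function(v) {
    if (length(v) < 2L) return(FALSE)
    kk <- min(2L, length(unique(v)))
    if (kk < 2L) return(FALSE)
    cz <- stats::kmeans(v, centers = kk, nstart = 10L)$centers
    diff(range(cz)) > 1  # > 1 order of magnitude apart
  }, logical(1L))
  res$alternative_equilibria <- flags
  class(res) <- "plastisim_patterns"
  res
}

#' @export
print.plastisim_patterns <- function(x, ...) {
  cat(sprintf("Cross-population patterns (%d/%d runs completed)\n",
              x$n_completed, x$n_total))
  if (!is.null(x$message)) {
    cat(" ", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Spearman(mean r, mean u)   = %+.3f\n", x$spearman_r_u))
  cat(sprintf("  Spearman(mean age, mean u) = %+.3f\n", x$spearman_age_u))
  cat(sprintf("  updating-frequency cluster centers (log10 u): %s\n",
              paste(sprintf("%.2f", x$clusters$centers_log10_u),
                    collapse = ", ")))
  n_flag <- sum(x$alternative_equilibria)
  cat(sprintf("  scenarios flagged for alternative equilibria: %d of %d\n",
              n_flag, length(x$alternative_equilibria)))
  invisible(x)
}

#' Scatter plots of evolved strategies across populations
#'
#' Base-graphics scatter plots of the cross-population relationships:
#' mean age vs mean `u`, mean `r` vs mean `u`, and mean mismatch vs mean
#' age, with points colored by environmental autocorrelation `p` and
#' shaped by updating error.
#'
#' @param x a [sweep_table()] data frame.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_sweep <- function(x, ...) {
  tab <- x[x$status == "completed", , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("no completed runs to plot")
    return(invisible(x))
  }
  pv <- sort(unique(tab$p))
  col <- grDevices::hcl.colors(max(2L, length(pv)), "viridis")[
    match(tab$p, pv)]
  pch <- c(21, 22, 23, 24)[match(tab$epsilon,
                                 sort(unique(tab$epsilon)))]
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$mean_u, tab$mean_age, log = "x", bg = col, pch = pch,
                 xlab = "evolved mean u", ylab = "mean age at t_max", ...)
  graphics::plot(tab$mean_u, tab$mean_r, log = "x", bg = col, pch = pch,
                 xlab = "evolved mean u", ylab = "evolved mean r", ...)
  graphics::plot(tab$mean_age, tab$mean_mismatch, bg = col, pch = pch,
                 xlab = "mean age at t_max", ylab = "mean mismatch", ...)
  invisible(x)
}
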