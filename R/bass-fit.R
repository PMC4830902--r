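#' Fit the Bass diffusion model to an observed adoption series
#'
#' Constrained nonlinear least-squares estimation of the innovation (`p`) and
#' imitation (`q`) coefficients for a fixed introduction year. The objective
#' is the sum of squared residuals between the closed-form cumulative curve
#' and the observed fractions, minimized subject to box bounds on `(p, q)`
#' and a per-year feasibility band: every absolute residual must stay within
#' `band` (default 0.02, i.e. 2 percentage points) of the data. Market
#' potential `m` is held fixed (default 1).
#'
#' The optimizer is deterministic: a coarse grid over `(log p, q)` is scanned,
#' the best `n_refine` grid points are polished with bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]), and the best
#' refined solution is returned. If the least-squares minimizer violates the
#' band, a penalized search for the best feasible pair is attempted; when no
#' feasible pair exists within the bounds the unconstrained minimizer is
#' returned with `feasible = FALSE`. Two runs on identical input yield
#' identical results.
#'
#' Degenerate series (constant or decreasing fractions) do not abort: the
#' bounded minimizer is returned, flagged by `feasible` and a warning, so
#' sensitivity tables over many start years always complete.
#'
#' @param series an `adoption_series` (or data frame with `year`, `fraction`);
#'   at least two points, all years after `start_year`.
#' @param start_year introduction year at which cumulative adoption is zero.
#' @param band feasibility band on the fraction scale: maximum allowed
#'   absolute residual per year (default 0.02 = 2 percentage points).
#' @param m fixed market potential in (0, 1].
#' @param p_bounds,q_bounds box bounds for the coefficients.
#' @param grid number of grid points for `log p` and `q` in the multi-start
#'   scan.
#' @param n_refine how many of the best grid points to polish.
#' @param refine_tol convergence tolerance of the local refinement.
#' @param label optional scenario label carried into forecasts.
#'
#' @return An object of class `bass_fit`: a list with components `params`
#'   ([bass_params()]), `series`, `predicted` (fractions), `residuals`
#'   (predicted minus observed, percentage-point scale), `objective` (sum of
#'   squared residuals on the fraction scale), `feasible`, `band`,
#'   `q_over_p`, `mean_difference` (mean signed residual, percentage points)
#'   and `label`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#'
#' @examples
#' obs <- adoption_series(data.frame(year = c(2008, 2011, 2013),
#'                                   fraction = c(0.0516, 0.0980, 0.1717)))
#' fit <- bass_fit(obs, start_year = 2001)
#' coef(fit)
#' summary(fit)
#' @export
bass_fit <- function(series, start_year, band = 0.02, m = 1,
                     p_bounds = c(1e-6, 0.5), q_bounds = c(0, 1),
                     grid = c(40L, 40L), n_refine = 5L,
                     refine_tol = 1e-12, label = NULL) {
  series <- as_series(series)
  if (nrow(series) < 2L) stop("adoption series must have at least 2 points")
  if (any(series$year <= start_year)) {
    stop("all series years must lie strictly after start_year = ", start_year)
  }
  stopifnot(band > 0, p_bounds[1] > 0, p_bounds[1] < p_bounds[2],
            q_bounds[1] >= 0, q_bounds[1] < q_bounds[2])
  tt <- series$year - start_year
  obs <- series$fraction

  resid_fun <- function(par) {
    e <- exp(-(par[1] + par[2]) * tt)
    m * (1 - e) / (1 + (par[2] / par[1]) * e) - obs
  }
  sse <- function(par) sum(resid_fun(par)^2)

  # deterministic multi-start: coarse scan over (log p, q)
  lp <- seq(log(p_bounds[1]), log(p_bounds[2]), length.out = grid[1])
  qq <- seq(q_bounds[1], q_bounds[2], length.out = grid[2])
  qq <- pmax(qq, 1e-12)  # q = 0 exactly is an admissible limit but LM starts
                         # better strictly inside
  cand <- expand.grid(p = exp(lp), q = qq)
  vals <- vapply(seq_len(nrow(cand)),
                 function(i) sse(c(cand$p[i], cand$q[i])), numeric(1))
  starts <- cand[order(vals)[seq_len(min(n_refine, nrow(cand)))], ,
                 drop = FALSE]

  refine <- function(start) {
    fit <- minpack.lm::nls.lm(
      par = c(start$p, start$q), fn = resid_fun,
      lower = c(p_bounds[1], q_bounds[1]),
      upper = c(p_bounds[2], q_bounds[2]),
      control = minpack.lm::nls.lm.control(
        ftol = refine_tol, ptol = refine_tol, gtol = 0, maxiter = 500)
    )
    fit$par
  }
  refined <- lapply(seq_len(nrow(starts)), function(i) refine(starts[i, ]))
  refined_sse <- vapply(refined, sse, numeric(1))
  best <- refined[[which.min(refined_sse)]]

  feas_tol <- band + 1e-12
  feasible <- max(abs(resid_fun(best))) <= feas_tol

  if (!feasible) {
    # look for the best pair satisfying the band via an exterior penalty
    pen <- function(par) {
      r <- resid_fun(par)
      sum(r^2) + 1e6 * sum(pmax(0, abs(r) - band)^2)
    }
    pen_try <- lapply(seq_len(nrow(starts)), function(i) {
      stats::optim(c(starts$p[i], starts$q[i]), pen, method = "L-BFGS-B",
                   lower = c(p_bounds[1], q_bounds[1]),
                   upper = c(p_bounds[2], q_bounds[2]),
                   control = list(factr = 1e3, maxit = 500))$par
    })
    pen_feasible <- vapply(pen_try,
                           function(par) max(abs(resid_fun(par))) <= feas_tol,
                           logical(1))
    if (any(pen_feasible)) {
      ok <- pen_try[pen_feasible]
      best <- ok[[which.min(vapply(ok, sse, numeric(1)))]]
      feasible <- TRUE
    } else {
      warning("no (p, q) within bounds keeps all residuals inside the ",
              band * 100, " percentage-point band; returning the ",
              "unconstrained least-squares minimizer")
    }
  }

  if (any(diff(obs) <= 0)) {
    warning("adoption series is not strictly increasing; Bass parameters ",
            "may be poorly identified")
  }

  params <- bass_params(p = best[1], q = best[2], m = m,
                        start_year = start_year)
  pred <- bass_cdf(params, tt)
  res_pct <- 100 * (pred - obs)
  structure(list(
    params = params,
    series = series,
    predicted = pred,
    residuals = res_pct,
    objective = sum((pred - obs)^2),
    feasible = feasible,
    band = band,
    q_over_p = params$q / params$p,
    mean_difference = mean(res_pct),
    label = if (is.null(label)) paste0(start_year, " start") else label,
    call = match.call()
  ), class = "bass_fit")
}

as_series <- function(series) {
  if (inherits(series, "adoption_series")) return(series)
  if (is.data.frame(series)) return(adoption_series(series))
  stop("`series` must be an adoption_series or a year/fraction data frame")
}

#' Start-date sensitivity analysis
#'
#' Refits the Bass model for each candidate introduction year and collects
#' the coefficients into one table (per row: `start_year`, `p`, `q`, `q/p`,
#' objective, feasibility). A failed fit for one start year is recorded and
#' does not abort the remaining rows.
#'
#' @inheritParams bass_fit
#' @param start_years integer vector of candidate introduction years, each
#'   before the first observed year.
#' @param ... further arguments passed to [bass_fit()].
#' @return An object of class `bass_sensitivity`: list with `fits` (named
#'   list of `bass_fit` or error condition) and `table` (data frame).
#' @export
bass_sensitivity <- function(series, start_years, ...) {
  series <- as_series(series)
  stopifnot(length(start_years) >= 1)
  fits <- lapply(start_years, function(sy) {
    tryCatch(bass_fit(series, start_year = sy, ...), error = identity)
  })
  names(fits) <- as.character(start_years)
  tab <- data.frame(
    start_year = as.integer(start_years),
    p = vapply(fits, function(f)
      if (inherits(f, "bass_fit")) f$params$p else NA_real_, numeric(1)),
    q = vapply(fits, function(f)
      if (inherits(f, "bass_fit")) f$params$q else NA_real_, numeric(1)),
    q_over_p = vapply(fits, function(f)
      if (inherits(f, "bass_fit")) f$q_over_p else NA_real_, numeric(1)),
    objective = vapply(fits, function(f)
      if (inherits(f, "bass_fit")) f$objective else NA_real_, numeric(1)),
    feasible = vapply(fits, function(f)
      if (inherits(f, "bass_fit")) f$feasible else NA, logical(1))
  )
  structure(list(fits = fits, table = tab, series = series),
            class = "bass_sensitivity")
}

#' @export
print.bass_sensitivity <- function(x, ...) {
  cat("Bass start-date sensitivity analysis\n")
  tab <- x$table
  tab$p <- signif(tab$p, 4)
  tab$q <- signif(tab$q, 4)
  tab$q_over_p <- round(tab$q_over_p, 3)
  tab$objective <- signif(tab$objective, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Leave-last-year-out stability check
#'
#' Refits the model with the final observation omitted and reports how much
#' the forecast at a horizon year moves. Small differences indicate the
#' fitted trajectory is not driven by the last data point alone.
#'
#' @inheritParams bass_fit
#' @param horizon_year calendar year at which the two forecasts are compared.
#' @param ... passed to [bass_fit()].
#' @return An object of class `bass_stability`: list with `fit_full`,
#'   `fit_reduced`, `horizon_year`, the two horizon fractions and
#'   `abs_difference` (fraction scale).
#' @export
bass_stability <- function(series, start_year, horizon_year, ...) {
  series <- as_series(series)
  if (nrow(series) < 3L) {
    stop("stability check needs at least 3 observed points")
  }
  fit_full <- bass_fit(series, start_year = start_year, ...)
  reduced <- series[-nrow(series), , drop = FALSE]
  fit_reduced <- bass_fit(reduced, start_year = start_year, ...)
  f_full <- bass_cdf(fit_full$params, horizon_year - start_year)
  f_red <- bass_cdf(fit_reduced$params, horizon_year - start_year)
  structure(list(
    fit_full = fit_full, fit_reduced = fit_reduced,
    horizon_year = as.integer(horizon_year),
    forecast_full = f_full, forecast_reduced = f_red,
    abs_difference = abs(f_full - f_red)
  ), class = "bass_stability")
}

#' @export
print.bass_stability <- function(x, ...) {
  cat("Leave-last-year-out stability check\n")
  cat(sprintf("  horizon year %d forecast, all data:    %.4f (%.2f%%)\n",
              x$horizon_year, x$forecast_full, 100 * x$forecast_full))
  cat(sprintf("  horizon year %d forecast, last omitted: %.4f (%.2f%%)\n",
              x$horizon_year, x$forecast_reduced, 100 * x$forecast_reduced))
  cat(sprintf("  absolute difference: %.4f (%.2f percentage points)\n",
              x$abs_difference, 100 * x$abs_difference))
  invisible(x)
}

#' Fit a diffusion curve through policy milestone targets
#'
#' Treats policy-mandated minimum engagement milestones (for example, 5%
#' of consumers communicating electronically by 2014 and 10% by 2017 under
#' the meaningful-use program) as if they were observed adoption and fits
#' the same constrained Bass model, yielding the diffusion trajectory the
#' policy targets imply.
#'
#' @param targets an `adoption_series` of (year, target fraction) milestones;
#'   at least two points. Defaults to [mu_targets()].
#' @inheritParams bass_fit
#' @param ... passed to [bass_fit()].
#' @return A `bass_fit` labelled `"MU targets"`.
#' @export
fit_policy_targets <- function(targets = mu_targets(), start_year = 2004,
                               ...) {
  bass_fit(targets, start_year = start_year, label = "MU targets", ...)
}

#' Default meaningful-use consumer-engagement milestones
#'
#' The stage 2 and stage 3 electronic-communication targets: 5% of consumers
#' by 2014 and 10% by 2017.
#'
#' @return An `adoption_series` with the two milestone points.
#' @export
mu_targets <- function() {
  adoption_series(data.frame(year = c(2014L, 2017L), fraction = c(0.05, 0.10)))
}
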