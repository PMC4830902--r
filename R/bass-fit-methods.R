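#' @export
print.bass_fit <- function(x, ...) {
  cat("Bass diffusion fit:", x$label, "\n")
  cat(sprintf("  p = %.6g, q = %.6g, q/p = %.3f, m = %g\n",
              x$params$p, x$params$q, x$q_over_p, x$params$m))
  cat(sprintf("  start year %d, %d observed years (%s)\n",
              x$params$start_year, nrow(x$series),
              paste(x$series$year, collapse = ", ")))
  cat(sprintf("  objective (SSE, fraction scale): %.3e\n", x$objective))
  cat(sprintf("  feasible within %.1f pp band: %s\n",
              100 * x$band, if (x$feasible) "yes" else "NO"))
  invisible(x)
}

#' @export
summary.bass_fit <- function(object, ...) {
  tab <- data.frame(
    year = object$series$year,
    observed_pct = 100 * object$series$fraction,
    predicted_pct = 100 * object$predicted,
    difference_pp = object$residuals
  )
  out <- list(
    label = object$label,
    params = object$params,
    q_over_p = object$q_over_p,
    shape = bass_shape(object$params),
    table = tab,
    mean_difference = object$mean_difference,
    max_abs_difference = max(abs(object$residuals)),
    objective = object$objective,
    feasible = object$feasible,
    band = object$band
  )
  class(out) <- "summary.bass_fit"
  out
}

#' @export
print.summary.bass_fit <- function(x, digits = 3, ...) {
  cat("Bass diffusion fit:", x$label, "\n\n")
  cat(sprintf("Coefficients: p = %.*g, q = %.*g (q/p = %.3f, %s)\n",
              digits, x$params$p, digits, x$params$q, x$q_over_p, x$shape))
  cat(sprintf("Start year: %d, market potential m = %g\n\n",
              x$params$start_year, x$params$m))
  tab <- x$table
  tab$observed_pct <- round(tab$observed_pct, 2)
  tab$predicted_pct <- round(tab$predicted_pct, 2)
  tab$difference_pp <- round(tab$difference_pp, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("\nMean difference: %.3f pp; max |difference|: %.3f pp\n",
              x$mean_difference, x$max_abs_difference))
  cat(sprintf("Feasible within %.1f pp band: %s\n",
              100 * x$band, if (x$feasible) "yes" else "NO"))
  invisible(x)
}

#' @export
coef.bass_fit <- function(object, ...) {
  c(p = object$params$p, q = object$params$q, m = object$params$m,
    start_year = as.numeric(object$params$start_year))
}

#' Predicted cumulative adoption at calendar years
#'
#' @param object a `bass_fit`.
#' @param years calendar years at which to evaluate the fitted curve;
#'   defaults to the observed survey years.
#' @param ... unused.
#' @return Numeric vector of cumulative adopted fractions.
#' @export
predict.bass_fit <- function(object, years = NULL, ...) {
  if (is.null(years)) return(object$predicted)
  bass_trajectory(object$params, years)$cumulative_fraction
}

#' @export
fitted.bass_fit <- function(object, ...) object$predicted

#' Fit residuals (predicted minus observed, percentage points)
#'
#' Sign convention follows the observed-versus-model difference tables this
#' model family is reported with: positive means the model over-predicts.
#'
#' @param object a `bass_fit`.
#' @param ... unused.
#' @export
residuals.bass_fit <- function(object, ...) {
  stats::setNames(object$residuals, object$series$year)
}

#' Plot an observed series against its fitted Bass curve
#'
#' @param x a `bass_fit`.
#' @param horizon_year rightmost year to draw; defaults to the last
#'   observed year.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bass_fit <- function(x, horizon_year = NULL, ...) {
  if (is.null(horizon_year)) horizon_year <- max(x$series$year)
  yrs <- x$params$start_year:horizon_year
  traj <- bass_trajectory(x$params, yrs)
  graphics::plot(traj$year, 100 * traj$cumulative_fraction, type = "l",
                 xlab = "Year", ylab = "Cumulative adoption (%)",
                 main = paste("Bass diffusion:", x$label), ...)
  graphics::points(x$series$year, 100 * x$series$fraction, pch = 19)
  graphics::legend("topleft", bty = "n", lty = c(1, NA), pch = c(NA, 19),
                   legend = c("fitted curve", "observed"))
  invisible(x)
}

#' Simulate observed adoption series from a fitted curve
#'
#' Draws binomial sampling noise around the fitted per-year fractions, at
#' the observed survey years, emulating re-running the survey with
#' `n_respondents` per year.
#'
#' @param object a `bass_fit`.
#' @param nsim number of replicate series.
#' @param seed optional integer seed; RNG state is restored afterwards.
#' @param n_respondents per-year sample size for the binomial draws.
#' @param ... unused.
#' @return A data frame with columns `sim`, `year`, `fraction`.
#' @export
simulate.bass_fit <- function(object, nsim = 1, seed = NULL,
                              n_respondents = 10000L, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  years <- object$series$year
  out <- do.call(rbind, lapply(seq_len(nsim), function(s) {
    data.frame(sim = s, year = years,
               fraction = stats::rbinom(length(years), n_respondents,
                                        object$predicted) / n_respondents)
  }))
  out
}
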