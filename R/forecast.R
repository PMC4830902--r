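#' Project a fitted scenario forward to a horizon year
#'
#' Evaluates the continuous closed form at every integer calendar year from
#' the scenario's start year to the horizon, producing the trajectory used
#' for scenario comparison and threshold analysis. At the observed years the
#' trajectory reproduces the fit's predicted values exactly — the same
#' closed form is evaluated, so there is no drift between fitting and
#' forecasting.
#'
#' @param fit a `bass_fit` or `bass_params` object.
#' @param horizon_year last calendar year of the projection; must lie after
#'   the start year.
#' @param label scenario label; defaults to the fit's label.
#' @return An object of class `bass_forecast`: list with `label`, `params`
#'   and `trajectory` (data frame `year`, `cumulative_fraction`, `percent`).
#' @examples
#' pars <- bass_params(p = 0.214 / 30.092, q = 0.214, start_year = 2004)
#' fc <- bass_forecast(pars, 2020)
#' threshold_year(fc, 0.25)
#' @export
bass_forecast <- function(fit, horizon_year, label = NULL) {
  params <- as_bass_params(fit)
  if (horizon_year <= params$start_year) {
    stop("horizon_year must lie after the start year ", params$start_year)
  }
  if (is.null(label)) {
    label <- if (inherits(fit, "bass_fit")) fit$label
    else paste0(params$start_year, " start")
  }
  traj <- bass_trajectory(params, params$start_year:horizon_year)
  structure(list(label = label, params = params, trajectory = traj),
            class = "bass_forecast")
}

#' @export
print.bass_forecast <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat("Bass forecast:", x$label, "\n")
  cat(sprintf("  years %d-%d; cumulative adoption %.2f%% at horizon\n",
              x$trajectory$year[1], x$trajectory$year[n],
              x$trajectory$percent[n]))
  invisible(x)
}

#' First calendar year a forecast reaches a target fraction
#'
#' Scans the annual trajectory for the first year whose cumulative fraction
#' meets or exceeds the target. Returns `NA` when the target is not reached
#' by the horizon. Targets at or above the market potential are unreachable
#' and raise an error. Consistent with the closed-form inverse: the result
#' equals `start_year + ceiling(bass_time_to_threshold(params, target))`
#' whenever the target is reached within the horizon.
#'
#' @param forecast a `bass_forecast`.
#' @param target_fraction fraction in `(0, m)`.
#' @return Integer calendar year, or `NA_integer_`.
#' @export
threshold_year <- function(forecast, target_fraction) {
  stopifnot(inherits(forecast, "bass_forecast"))
  if (target_fraction >= forecast$params$m) {
    stop("target_fraction must be below the market potential m = ",
         forecast$params$m)
  }
  if (target_fraction <= 0) stop("target_fraction must be positive")
  hit <- which(forecast$trajectory$cumulative_fraction >= target_fraction)
  if (length(hit) == 0L) return(NA_integer_)
  forecast$trajectory$year[hit[1]]
}

#' Compare scenario forecasts against a reference trajectory
#'
#' Aligns forecasts on the calendar years common to all of them (years
#' before a scenario's start contribute zero adoption by construction of
#' [bass_trajectory()]) and reports each scenario's per-year difference from
#' the reference scenario, plus which scenario dominates at the horizon.
#' Swapping scenario and reference negates every difference.
#'
#' @param forecasts list of `bass_forecast` objects with distinct labels.
#' @param reference_label label of the reference scenario.
#' @return An object of class `scenario_comparison`: list with `table`
#'   (long data frame `year`, `label`, `cumulative_fraction`,
#'   `difference_vs_reference`), `reference_label`, `horizon_year` and
#'   `dominant_label` (highest adoption at the horizon).
#' @export
compare_scenarios <- function(forecasts, reference_label) {
  stopifnot(is.list(forecasts), length(forecasts) >= 2L,
            all(vapply(forecasts, inherits, TRUE, "bass_forecast")))
  labels <- vapply(forecasts, function(f) f$label, character(1))
  if (anyDuplicated(labels)) stop("forecast labels must be distinct")
  if (!reference_label %in% labels) {
    stop("reference label ", sQuote(reference_label),
         " not found among: ", paste(labels, collapse = ", "))
  }
  years <- Reduce(intersect, lapply(forecasts, function(f) f$trajectory$year))
  if (length(years) == 0L) stop("forecasts share no common years")
  years <- sort(years)
  val_at <- function(f) {
    f$trajectory$cumulative_fraction[match(years, f$trajectory$year)]
  }
  ref <- val_at(forecasts[[match(reference_label, labels)]])
  tab <- do.call(rbind, lapply(forecasts, function(f) {
    v <- val_at(f)
    data.frame(year = years, label = f$label, cumulative_fraction = v,
               difference_vs_reference = v - ref)
  }))
  horizon <- max(years)
  at_h <- tab[tab$year == horizon, ]
  structure(list(
    table = tab,
    reference_label = reference_label,
    horizon_year = horizon,
    dominant_label = at_h$label[which.max(at_h$cumulative_fraction)]
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison vs", sQuote(x$reference_label), "\n")
  at_h <- x$table[x$table$year == x$horizon_year, ]
  at_h$cumulative_fraction <- round(100 * at_h$cumulative_fraction, 2)
  at_h$difference_vs_reference <- round(100 * at_h$difference_vs_reference, 2)
  names(at_h) <- c("year", "label", "adoption_pct_at_horizon",
                   "difference_pp")
  print(at_h, row.names = FALSE)
  cat("Dominant scenario at", x$horizon_year, "horizon:",
      x$dominant_label, "\n")
  invisible(x)
}
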