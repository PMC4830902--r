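#' Bass diffusion model parameters
#'
#' Container for the parameters of the Bass mixed-influence diffusion model:
#' the external (innovation) coefficient `p`, the internal (imitation,
#' word-of-mouth) coefficient `q`, the market potential `m` expressed as a
#' fraction of the population, and the calendar year `start_year` at which
#' cumulative adoption is defined to be zero.
#'
#' The adoption hazard at time `t` is `p + q * F(t) / m` acting on the
#' not-yet-adopted fraction `m - F(t)`, so `p` captures adoption pressure
#' independent of the installed base (advertising, policy, availability) and
#' `q` captures social contagion proportional to it. Large `q/p` produces the
#' slow-start, late-acceleration S-curve typical of high-risk innovations.
#'
#' @param p external influence coefficient, strictly positive.
#' @param q internal influence coefficient, nonnegative.
#' @param m market potential as a fraction of the population, in (0, 1].
#'   Defaults to 1: the whole population can eventually adopt.
#' @param start_year calendar year at which cumulative adoption is zero.
#'
#' @return An object of class `bass_params`.
#' @examples
#' bass_params(p = 0.007, q = 0.214, start_year = 2004)
#' @export
bass_params <- function(p, q, m = 1, start_year = 2001L) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(q), length(q) == 1L,
            is.numeric(m), length(m) == 1L, is.numeric(start_year),
            length(start_year) == 1L)
  if (!is.finite(p) || p <= 0) stop("`p` must be a finite positive number")
  if (!is.finite(q) || q < 0) stop("`q` must be a finite nonnegative number")
  if (!is.finite(m) || m <= 0 || m > 1) stop("`m` must lie in (0, 1]")
  structure(list(p = p, q = q, m = m, start_year = as.integer(start_year)),
            class = "bass_params")
}

#' @export
print.bass_params <- function(x, ...) {
  cat("Bass diffusion parameters\n")
  cat(sprintf("  p (external/innovation): %.6g\n", x$p))
  cat(sprintf("  q (internal/imitation):  %.6g\n", x$q))
  cat(sprintf("  q/p ratio:               %.4f\n", x$q / x$p))
  cat(sprintf("  market potential m:      %g\n", x$m))
  cat(sprintf("  start year:              %d\n", x$start_year))
  cat(sprintf("  curve shape:             %s\n", bass_shape(x)))
  invisible(x)
}

as_bass_params <- function(x) {
  if (inherits(x, "bass_params")) return(x)
  if (inherits(x, "bass_fit")) return(x$params)
  stop("expected a `bass_params` or `bass_fit` object")
}

#' Cumulative adoption under the Bass model
#'
#' Closed-form cumulative adopted fraction
#' `F(t) = m * (1 - exp(-(p+q) t)) / (1 + (q/p) exp(-(p+q) t))`
#' at `t` years since the start year. With `q = 0` the expression reduces
#' analytically to the pure external (exponential) model `m * (1 - exp(-p t))`,
#' which the same formula yields since `q/p = 0`.
#'
#' @param params a [bass_params()] object.
#' @param t nonnegative numeric vector, years elapsed since `start_year`.
#' @return Numeric vector of cumulative adopted fractions in `[0, m)`.
#' @examples
#' pars <- bass_params(p = 0.268 / 117.040, q = 0.268, start_year = 2001)
#' bass_cdf(pars, 7) # cumulative fraction 7 years after introduction
#' @export
bass_cdf <- function(params, t) {
  params <- as_bass_params(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be nonnegative (years since the start year)")
  }
  e <- exp(-(params$p + params$q) * t)
  params$m * (1 - e) / (1 + (params$q / params$p) * e)
}

#' Instantaneous adoption rate dF/dt
#'
#' Derivative of [bass_cdf()]: `(p + q F/m) (m - F)`, the hazard applied to
#' the remaining market. Used for inflection diagnostics.
#'
#' @inheritParams bass_cdf
#' @return Numeric vector of nonnegative rates (fraction per year).
#' @export
bass_rate <- function(params, t) {
  params <- as_bass_params(params)
  f <- bass_cdf(params, t)
  (params$p + params$q * f / params$m) * (params$m - f)
}

#' Annual-step discrete Bass recursion
#'
#' Discrete-time counterpart of the continuous model:
#' `N_t = N_{t-1} + (p + q N_{t-1} / m) (m - N_{t-1}) * dt`, `N_0 = 0`,
#' with `dt = 1 / steps_per_year`. The first annual increment is `p * m`.
#' Provided as a diagnostic; the closed form is the evaluator used for
#' fitting and forecasting. As `dt -> 0` the terminal value converges to
#' [bass_cdf()] at the horizon.
#'
#' @inheritParams bass_cdf
#' @param n_steps number of steps to take (at least 1).
#' @param steps_per_year sub-annual refinement factor, default 1.
#' @return Data frame with columns `t` (years since start), `year` (calendar,
#'   fractional when refined) and `cumulative_fraction`.
#' @export
bass_discrete_trajectory <- function(params, n_steps, steps_per_year = 1L) {
  params <- as_bass_params(params)
  stopifnot(n_steps >= 1, steps_per_year >= 1)
  dt <- 1 / steps_per_year
  n <- numeric(n_steps + 1L)
  for (i in seq_len(n_steps)) {
    gain <- (params$p + params$q * n[i] / params$m) * (params$m - n[i]) * dt
    n[i + 1L] <- n[i] + gain
  }
  tt <- (0:n_steps) * dt
  data.frame(t = tt, year = params$start_year + tt, cumulative_fraction = n)
}

#' Inflection point of the adoption curve
#'
#' For an S-shaped curve (`q > p`) the adoption rate peaks at
#' `t* = log(q/p) / (p + q)` years after the start. When `q <= p` the curve
#' is an inverse J (monotone decelerating) with no interior inflection and
#' `NA` is returned.
#'
#' @inheritParams bass_cdf
#' @return Time of peak adoption rate in years since start, or `NA_real_`.
#' @export
bass_inflection_time <- function(params) {
  params <- as_bass_params(params)
  if (params$q <= params$p) return(NA_real_)
  log(params$q / params$p) / (params$p + params$q)
}

#' Time until a target adoption fraction is reached
#'
#' Inverts [bass_cdf()] in closed form:
#' `t = -log((m - F) / (m + (q/p) F)) / (p + q)`.
#'
#' @inheritParams bass_cdf
#' @param target_fraction fraction in `[0, m)`; values at or above the market
#'   potential are never reached and raise an error.
#' @return Years since `start_year` at which the target is attained.
#' @export
bass_time_to_threshold <- function(params, target_fraction) {
  params <- as_bass_params(params)
  if (any(target_fraction < 0) || any(target_fraction >= params$m)) {
    stop("`target_fraction` must lie in [0, m): targets at or above the ",
         "market potential are unreachable")
  }
  e <- (params$m - target_fraction) /
    (params$m + (params$q / params$p) * target_fraction)
  -log(e) / (params$p + params$q)
}

#' Classify the cumulative adoption curve shape
#'
#' `"s_curve"` when the imitation coefficient strictly exceeds the innovation
#' coefficient (`q > p`, interior inflection point), `"inverse_j"` otherwise
#' (including the boundary `q == p`).
#'
#' @inheritParams bass_cdf
#' @return `"s_curve"` or `"inverse_j"`.
#' @export
bass_shape <- function(params) {
  params <- as_bass_params(params)
  if (params$q > params$p) "s_curve" else "inverse_j"
}

#' Motivation coefficient ratio q/p
#'
#' The ratio of internal (imitation) to external (innovation) influence. High
#' values indicate word-of-mouth-dominated diffusion: a slow start followed by
#' late acceleration.
#'
#' @inheritParams bass_cdf
#' @return Nonnegative number `q / p`.
#' @export
motivation_ratio <- function(params) {
  params <- as_bass_params(params)
  if (params$p <= 0) stop("`p` must be positive")
  params$q / params$p
}

#' Cumulative adoption trajectory over calendar years
#'
#' Evaluates the continuous closed form at integer calendar years. Years at or
#' before the start year report zero adoption, so scenarios with different
#' start dates can be aligned on a common calendar grid.
#'
#' @inheritParams bass_cdf
#' @param years integer vector of calendar years.
#' @return Data frame with columns `year`, `cumulative_fraction`, `percent`.
#' @export
bass_trajectory <- function(params, years) {
  params <- as_bass_params(params)
  tt <- pmax(years - params$start_year, 0)
  f <- bass_cdf(params, tt)
  data.frame(year = as.integer(years), cumulative_fraction = f,
             percent = 100 * f)
}
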