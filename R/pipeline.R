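#' Run the full tabulate-fit-forecast pipeline from one configuration
#'
#' Orchestrates the complete analysis: load a respondent-level survey CSV
#' (or a pre-tabulated adoption-series CSV), tabulate the weighted joint
#' categories per year, fit the constrained Bass model for each candidate
#' start year, fit the policy-target curve, project every scenario to the
#' horizon, compare scenarios, and write all artifacts (CSV tables, a
#' trajectory file, and a machine-readable JSON summary) to an output
#' directory. The run is deterministic: repeating it with the same
#' configuration reproduces the same files byte for byte.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   fields:
#'   \describe{
#'     \item{survey_csv / series_csv}{exactly one: respondent-level survey
#'       CSV, or year/fraction series CSV.}
#'     \item{targets_csv}{optional policy-milestone CSV (year, fraction);
#'       when absent the default meaningful-use milestones [mu_targets()]
#'       are used.}
#'     \item{missing_policy}{`"exclude"` (default) or `"treat_as_no"`.}
#'     \item{start_years}{candidate introduction years, default
#'       `c(2001, 2004, 2007)`.}
#'     \item{policy_start_year}{start year for the policy curve, default
#'       2004.}
#'     \item{band}{feasibility band, default 0.02.}
#'     \item{horizon_year}{forecast horizon, default 2020.}
#'     \item{out_dir}{output directory, created if needed.}
#'     \item{verbose}{emit progress messages, default `TRUE`.}
#'   }
#' @return Invisibly, a list with the fitted objects, the comparison, the
#'   resolved configuration and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(missing_policy = "exclude",
                   start_years = c(2001L, 2004L, 2007L),
                   policy_start_year = 2004L,
                   band = 0.02, horizon_year = 2020L,
                   out_dir = "bassadopt-output", verbose = TRUE)
  cfg <- utils::modifyList(defaults, config)
  has_survey <- !is.null(cfg$survey_csv)
  has_series <- !is.null(cfg$series_csv)
  if (has_survey == has_series) {
    stop("provide exactly one of `survey_csv` or `series_csv`")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(cfg$verbose)) message("[bassadopt] ", ...)
  paths <- list()

  # stage 1: observed series (tabulating the survey if that is the input)
  if (has_survey) {
    say("loading survey: ", cfg$survey_csv)
    records <- read_survey(cfg$survey_csv)
    years <- sort(unique(records$survey_year))
    tables <- lapply(years, function(y) {
      tabulate_adoption(records, y, missing_policy = cfg$missing_policy)
    })
    tab_df <- do.call(rbind, lapply(tables, function(tb) {
      data.frame(survey_year = tb$survey_year,
                 category = names(tb$counts),
                 weighted_count = unname(tb$counts),
                 percent = unname(tb$percent))
    }))
    paths$tabulation <- file.path(cfg$out_dir, "tabulation.csv")
    utils::write.csv(tab_df, paths$tabulation, row.names = FALSE)
    say("tabulated ", length(years), " survey years (missing_policy = ",
        cfg$missing_policy, ")")
    series <- adoption_series(tables)
  } else {
    say("loading adoption series: ", cfg$series_csv)
    series <- read_adoption_series(cfg$series_csv)
  }
  paths$series <- file.path(cfg$out_dir, "adoption_series.csv")
  utils::write.csv(as.data.frame(series), paths$series, row.names = FALSE)

  # stage 2: start-date sensitivity fits
  say("fitting Bass model for start years ",
      paste(cfg$start_years, collapse = ", "))
  sens <- bass_sensitivity(series, cfg$start_years, band = cfg$band)
  paths$coefficients <- file.path(cfg$out_dir, "coefficients.csv")
  utils::write.csv(sens$table, paths$coefficients, row.names = FALSE)

  obs_pred <- do.call(rbind, lapply(sens$fits, function(f) {
    if (!inherits(f, "bass_fit")) return(NULL)
    data.frame(start_year = f$params$start_year,
               year = f$series$year,
               observed_pct = 100 * f$series$fraction,
               predicted_pct = 100 * f$predicted,
               difference_pp = f$residuals)
  }))
  paths$observed_vs_predicted <- file.path(cfg$out_dir,
                                           "observed_vs_predicted.csv")
  utils::write.csv(obs_pred, paths$observed_vs_predicted, row.names = FALSE)

  # stage 3: policy-target curve
  targets <- if (!is.null(cfg$targets_csv)) {
    say("loading policy targets: ", cfg$targets_csv)
    read_adoption_series(cfg$targets_csv)
  } else {
    say("using default meaningful-use milestones")
    mu_targets()
  }
  mu_fit <- fit_policy_targets(targets, start_year = cfg$policy_start_year,
                               band = cfg$band)

  # stage 4: forecasts and comparison
  say("projecting scenarios to ", cfg$horizon_year)
  ok_fits <- Filter(function(f) inherits(f, "bass_fit"), sens$fits)
  forecasts <- c(lapply(ok_fits, bass_forecast,
                        horizon_year = cfg$horizon_year),
                 list(bass_forecast(mu_fit, cfg$horizon_year)))
  traj <- do.call(rbind, lapply(forecasts, function(fc) {
    cbind(label = fc$label, fc$trajectory)
  }))
  paths$trajectories <- file.path(cfg$out_dir, "trajectories.csv")
  utils::write.csv(traj, paths$trajectories, row.names = FALSE)
  comparison <- compare_scenarios(forecasts, "MU targets")
  paths$comparison <- file.path(cfg$out_dir, "scenario_comparison.csv")
  utils::write.csv(comparison$table, paths$comparison, row.names = FALSE)

  # stage 5: JSON summary (resolved config included so runs self-describe)
  summary_obj <- list(
    config = cfg[c("missing_policy", "start_years", "policy_start_year",
                   "band", "horizon_year")],
    series = as.data.frame(series),
    fits = lapply(sens$fits, function(f) {
      if (!inherits(f, "bass_fit")) {
        return(list(error = conditionMessage(f)))
      }
      list(label = f$label, p = f$params$p, q = f$params$q,
           m = f$params$m, start_year = f$params$start_year,
           q_over_p = f$q_over_p, objective = f$objective,
           feasible = f$feasible, residuals_pp = f$residuals)
    }),
    policy_fit = list(label = mu_fit$label, p = mu_fit$params$p,
                      q = mu_fit$params$q,
                      start_year = mu_fit$params$start_year,
                      q_over_p = mu_fit$q_over_p,
                      feasible = mu_fit$feasible),
    horizon = list(
      year = cfg$horizon_year,
      adoption_pct = stats::setNames(
        lapply(forecasts, function(fc) {
          utils::tail(fc$trajectory$percent, 1)
        }),
        vapply(forecasts, function(fc) fc$label, character(1))),
      dominant = comparison$dominant_label)
  )
  paths$summary <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", length(paths), " artifacts to ", cfg$out_dir)

  invisible(list(series = series, sensitivity = sens, policy_fit = mu_fit,
                 forecasts = forecasts, comparison = comparison,
                 config = cfg, paths = paths))
}
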