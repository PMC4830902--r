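#' Design for a synthetic weighted survey experiment
#'
#' Describes a multi-year weighted cross-sectional survey whose true joint
#' PHR-use prevalence follows a Bass curve, so the whole pipeline
#' (tabulate, fit, forecast) can be exercised end-to-end with known truth.
#' Defaults emulate the structure of the 2008/2011/2013 survey rounds:
#' roughly 150-180 million weighted population per round, single-item use in
#' the 8-13% (communication only) and 9-11% (tracking only) bands, and a
#' joint-use truth in the diffusion regime observed for consumer health
#' technologies.
#'
#' @param p,q,start_year,m true Bass parameters of the joint-use prevalence.
#' @param survey_years calendar years of the survey rounds, all after
#'   `start_year`.
#' @param n_per_year respondents sampled per round.
#' @param target_population weighted population each round's weights sum to;
#'   scalar or one value per round. `NULL` (default) spans 153 to 182
#'   million across the rounds.
#' @param comm_only_rate,track_only_rate per-round marginal rates of
#'   single-item use; scalar or one value per round. `NULL` (default) spans
#'   8.4-12.6% (communication only) and 9.1-11.0% (tracking only). Together
#'   with the Bass joint-use truth they must leave a nonnegative both-no
#'   remainder.
#' @param weight_dispersion coefficient of variation of the sampling weights
#'   around their round mean (gamma-shaped, unit mean); 0 gives equal
#'   weights.
#' @param noise `"binomial"` draws each round's category counts from a
#'   multinomial; `"none"` allocates expected counts deterministically
#'   (largest-remainder rounding).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(p = 0.007, q = 0.214, start_year = 2004, m = 1,
                             survey_years = c(2008L, 2011L, 2013L),
                             n_per_year = 10000L,
                             target_population = NULL,
                             comm_only_rate = NULL,
                             track_only_rate = NULL,
                             weight_dispersion = 0.5,
                             noise = c("binomial", "none"),
                             seed = 1L) {
  noise <- match.arg(noise)
  truth <- bass_params(p = p, q = q, m = m, start_year = start_year)
  ny <- length(survey_years)
  stopifnot(ny >= 1, n_per_year >= 1, weight_dispersion >= 0)
  if (any(survey_years <= start_year)) {
    stop("all survey_years must lie after the truth start_year")
  }
  # per-year defaults span the bands seen in the motivating survey rounds
  defaults <- function(lo, hi) if (ny == 1L) lo else
    seq(lo, hi, length.out = ny)
  if (is.null(target_population)) {
    target_population <- defaults(1.53e8, 1.82e8)
  }
  if (is.null(comm_only_rate)) comm_only_rate <- defaults(0.084, 0.126)
  if (is.null(track_only_rate)) track_only_rate <- defaults(0.091, 0.110)
  expand <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, ny)
    if (length(x) != ny) {
      stop("`", name, "` must have length 1 or length(survey_years)")
    }
    x
  }
  target_population <- expand(target_population, "target_population")
  comm_only_rate <- expand(comm_only_rate, "comm_only_rate")
  track_only_rate <- expand(track_only_rate, "track_only_rate")
  both <- bass_cdf(truth, survey_years - start_year)
  if (any(both + comm_only_rate + track_only_rate > 1)) {
    stop("joint-use truth plus single-item rates exceed 1 in some year: ",
         "category probabilities must lie in the simplex")
  }
  structure(list(
    truth = truth, survey_years = as.integer(survey_years),
    n_per_year = as.integer(n_per_year),
    target_population = target_population,
    comm_only_rate = comm_only_rate, track_only_rate = track_only_rate,
    weight_dispersion = weight_dispersion, noise = noise,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic survey design\n")
  cat(sprintf("  truth: p = %g, q = %g, m = %g, start %d\n",
              x$truth$p, x$truth$q, x$truth$m, x$truth$start_year))
  cat(sprintf("  rounds: %s; n = %d per round; noise = %s; seed = %d\n",
              paste(x$survey_years, collapse = ", "), x$n_per_year,
              x$noise, x$seed))
  invisible(x)
}

# Round expected counts to integers summing to n (largest remainder).
allocate_counts <- function(probs, n) {
  raw <- probs * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a respondent-level synthetic survey
#'
#' For each survey round: weights are drawn first (gamma-shaped dispersion,
#' rescaled so they sum to the round's target population), then respondents
#' are assigned to the four joint response categories with probabilities
#' (Bass joint-use truth, comm-only rate, track-only rate, remainder) —
#' multinomial draws under `noise = "binomial"`, expected counts under
#' `noise = "none"`. In deterministic mode each category's weights are
#' additionally rescaled so the category carries exactly its probability
#' mass, making weighted shares reproduce the design probabilities up to
#' count rounding. Rounds are processed in year order with this fixed
#' sub-stream order, so a given seed always reproduces the same dataset.
#' The RNG state of the session is restored on exit.
#'
#' @param design a [synthetic_design()].
#' @return A `survey_records` data frame, one row per respondent.
#' @examples
#' des <- synthetic_design(n_per_year = 500, seed = 7)
#' rec <- generate_population(des)
#' adoption_series(rec)
#' @export
generate_population <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(design$seed)

  n <- design$n_per_year
  rounds <- lapply(seq_along(design$survey_years), function(i) {
    year <- design$survey_years[i]
    # weights first
    w <- if (design$weight_dispersion > 0) {
      shape <- 1 / design$weight_dispersion^2
      stats::rgamma(n, shape = shape, rate = shape)
    } else rep(1, n)
    w <- w * design$target_population[i] / sum(w)
    # then joint categories
    f <- bass_cdf(design$truth, year - design$truth$start_year)
    probs <- c(both_yes = f,
               comm_only = design$comm_only_rate[i],
               track_only = design$track_only_rate[i],
               both_no = 1 - f - design$comm_only_rate[i] -
                 design$track_only_rate[i])
    counts <- if (design$noise == "binomial") {
      as.integer(stats::rmultinom(1, n, probs))
    } else {
      allocate_counts(probs, n)
    }
    cat_lab <- rep(names(probs), counts)
    if (design$noise == "none") {
      # deterministic mode guarantees weighted category shares equal the
      # design probabilities: rescale each represented category's weights
      # to carry exactly its probability mass
      represented <- which(counts > 0)
      share <- probs[represented] / sum(probs[represented])
      total_w <- sum(w)
      for (k in seq_along(represented)) {
        sel <- cat_lab == names(probs)[represented[k]]
        w[sel] <- w[sel] * share[k] * total_w / sum(w[sel])
      }
      w <- w * design$target_population[i] / sum(w)
    }
    data.frame(
      respondent_id = sprintf("Y%d_%06d", year, seq_len(n)),
      survey_year = year,
      weight = w,
      item_track = ifelse(cat_lab %in% c("both_yes", "track_only"),
                          "yes", "no"),
      item_comm = ifelse(cat_lab %in% c("both_yes", "comm_only"),
                         "yes", "no"),
      stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, rounds)
  survey_records(all$respondent_id, all$survey_year, all$weight,
                 all$item_track, all$item_comm)
}

#' Parameter-recovery experiment over replicate synthetic surveys
#'
#' Generates `n_replicates` independent synthetic surveys from the design
#' (replicate r uses seed `design$seed + r`), runs each through the full
#' pipeline (tabulate, adoption series, constrained Bass fit at the true
#' start year) and summarizes recovery of `(p, q)`: per-replicate estimates,
#' bias, RMSE, and the fraction of replicates whose fit is feasible within
#' the band.
#'
#' @param design a [synthetic_design()].
#' @param n_replicates number of replicate surveys (at least 1).
#' @param band feasibility band passed to [bass_fit()].
#' @param ... further arguments passed to [bass_fit()].
#' @return An object of class `recovery_report`: list with `estimates`
#'   (data frame `replicate`, `p_hat`, `q_hat`, `feasible`, `objective`),
#'   `truth`, `bias` (named), `rmse` (named) and `feasible_fraction`.
#' @export
recovery_experiment <- function(design, n_replicates, band = 0.02, ...) {
  stopifnot(inherits(design, "synthetic_design"), n_replicates >= 1)
  rows <- lapply(seq_len(n_replicates), function(r) {
    des_r <- design
    des_r$seed <- design$seed + r
    res <- tryCatch({
      rec <- generate_population(des_r)
      ser <- adoption_series(rec)
      fit <- bass_fit(ser, start_year = design$truth$start_year,
                      band = band, m = design$truth$m, ...)
      data.frame(replicate = r, p_hat = fit$params$p, q_hat = fit$params$q,
                 feasible = fit$feasible, objective = fit$objective)
    }, error = function(e) {
      stop("replicate ", r, " failed: ", conditionMessage(e))
    })
    res
  })
  est <- do.call(rbind, rows)
  truth <- c(p = design$truth$p, q = design$truth$q)
  bias <- c(p = mean(est$p_hat) - truth["p"],
            q = mean(est$q_hat) - truth["q"])
  rmse <- c(p = sqrt(mean((est$p_hat - truth["p"])^2)),
            q = sqrt(mean((est$q_hat - truth["q"])^2)))
  structure(list(
    estimates = est, truth = truth,
    bias = stats::setNames(as.numeric(bias), c("p", "q")),
    rmse = stats::setNames(as.numeric(rmse), c("p", "q")),
    feasible_fraction = mean(est$feasible)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Bass parameter recovery over", nrow(x$estimates), "replicates\n")
  cat(sprintf("  truth: p = %g, q = %g\n", x$truth["p"], x$truth["q"]))
  cat(sprintf("  bias:  p %+0.5f, q %+0.5f\n", x$bias["p"], x$bias["q"]))
  cat(sprintf("  RMSE:  p %0.5f, q %0.5f\n", x$rmse["p"], x$rmse["q"]))
  cat(sprintf("  feasible fits: %.0f%%\n", 100 * x$feasible_fraction))
  invisible(x)
}
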