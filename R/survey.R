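#' Read respondent-level two-item survey records
#'
#' Loads a CSV of respondent-level records from a weighted cross-sectional
#' survey measuring two binary PHR-functionality items: tracking personal
#' health information online and communicating electronically with a care
#' provider. Item responses are normalized case-insensitively to
#' `"yes"` / `"no"`; empty cells, `NA` and `"missing"` become `"missing"`.
#'
#' @param path path to a CSV with header columns
#'   `respondent_id, survey_year, weight, item_track, item_comm`.
#' @param year_range valid calendar-year range for `survey_year`.
#' @return A data frame of class `survey_records`.
#' @export
read_survey <- function(path, year_range = c(1990L, 2100L)) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), strip.white = TRUE)
  required <- c("respondent_id", "survey_year", "weight",
                "item_track", "item_comm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("survey CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  survey_records(
    respondent_id = raw$respondent_id,
    survey_year = suppressWarnings(as.integer(raw$survey_year)),
    weight = suppressWarnings(as.numeric(raw$weight)),
    item_track = raw$item_track,
    item_comm = raw$item_comm,
    year_range = year_range
  )
}

#' Construct validated survey records
#'
#' In-memory constructor behind [read_survey()]; also used by the synthetic
#' generator. Validates weights and years and normalizes item responses.
#'
#' @param respondent_id character vector of opaque respondent identifiers.
#' @param survey_year integer calendar years.
#' @param weight nonnegative sampling weights scaling to the population.
#' @param item_track,item_comm item responses; any casing of yes/no, with
#'   `""`, `NA` or `"missing"` treated as missing.
#' @param year_range valid calendar-year range.
#' @return A data frame of class `survey_records` with columns
#'   `respondent_id`, `survey_year`, `weight`, `item_track`, `item_comm`.
#' @export
survey_records <- function(respondent_id, survey_year, weight,
                           item_track, item_comm,
                           year_range = c(1990L, 2100L)) {
  n <- length(respondent_id)
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  survey_year <- recycle(survey_year)
  weight <- recycle(weight)
  item_track <- recycle(item_track)
  item_comm <- recycle(item_comm)
  stopifnot(length(survey_year) == n, length(weight) == n,
            length(item_track) == n, length(item_comm) == n)
  if (anyNA(survey_year) || any(survey_year < year_range[1]) ||
      any(survey_year > year_range[2])) {
    bad <- which(is.na(survey_year) | survey_year < year_range[1] |
                   survey_year > year_range[2])[1]
    stop("invalid survey_year in row ", bad,
         " (valid range ", year_range[1], "-", year_range[2], ")")
  }
  if (anyNA(weight) || any(weight < 0)) {
    bad <- which(is.na(weight) | weight < 0)[1]
    stop("negative or non-numeric weight in row ", bad)
  }
  out <- data.frame(
    respondent_id = as.character(respondent_id),
    survey_year = as.integer(survey_year),
    weight = as.numeric(weight),
    item_track = normalize_item(item_track, "item_track"),
    item_comm = normalize_item(item_comm, "item_comm"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("survey_records", "data.frame")
  out
}

normalize_item <- function(x, name) {
  v <- tolower(trimws(as.character(x)))
  v[is.na(v) | v == "" | v == "na"] <- "missing"
  bad <- !(v %in% c("yes", "no", "missing"))
  if (any(bad)) {
    stop("unrecognized ", name, " value ", sQuote(x[which(bad)[1]]),
         " in row ", which(bad)[1], " (expected yes/no/empty)")
  }
  v
}

#' Weighted joint-category tabulation for one survey year
#'
#' Cross-tabulates the two PHR items into the four joint categories
#' (`both_yes`, `comm_only`, `track_only`, `both_no`) using the sampling
#' weights, so counts scale to the target population. Percentages are
#' `100 * category / total`. The four weighted counts always sum to the
#' total, and rescaling all weights by a positive constant leaves every
#' percentage unchanged.
#'
#' @param records a `survey_records` data frame.
#' @param year survey year to tabulate.
#' @param missing_policy `"exclude"` drops respondents missing either item
#'   (listwise deletion, the default); `"treat_as_no"` recodes missing to no.
#' @return An object of class `adoption_table`: a list with `survey_year`,
#'   named `counts`, `total` and named `percent` (full precision; round for
#'   display).
#' @export
tabulate_adoption <- function(records, year,
                              missing_policy = c("exclude", "treat_as_no")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(records, "data.frame"))
  r <- records[records$survey_year == year, , drop = FALSE]
  if (missing_policy == "exclude") {
    r <- r[r$item_track != "missing" & r$item_comm != "missing", , drop = FALSE]
  } else {
    r$item_track[r$item_track == "missing"] <- "no"
    r$item_comm[r$item_comm == "missing"] <- "no"
  }
  if (nrow(r) == 0L) {
    stop("no usable records for survey year ", year,
         " under missing_policy = ", sQuote(missing_policy))
  }
  track <- r$item_track == "yes"
  comm <- r$item_comm == "yes"
  counts <- c(
    both_yes = sum(r$weight[track & comm]),
    comm_only = sum(r$weight[!track & comm]),
    track_only = sum(r$weight[track & !comm]),
    both_no = sum(r$weight[!track & !comm])
  )
  total <- sum(r$weight)
  structure(list(
    survey_year = as.integer(year),
    counts = counts,
    total = total,
    percent = 100 * counts / total
  ), class = "adoption_table")
}

#' @export
print.adoption_table <- function(x, digits = 2, ...) {
  cat("Weighted adoption table, survey year", x$survey_year, "\n")
  df <- data.frame(
    category = names(x$counts),
    weighted_count = unname(x$counts),
    percent = round(unname(x$percent), digits)
  )
  print(df, row.names = FALSE)
  cat("total:", format(x$total, big.mark = ","), "\n")
  invisible(x)
}

#' Build the joint-use adoption series for Bass fitting
#'
#' Extracts per-year adoption fractions (`both_yes / total`) from a set of
#' single-year tabulations, or tabulates a `survey_records` data frame over
#' all its years first. The result is the observed uptake series the Bass
#' model is fitted to.
#'
#' @param x a list of [tabulate_adoption()] results, a `survey_records` data
#'   frame, or a data frame with `year` and `fraction` columns.
#' @param ... passed to [tabulate_adoption()] when `x` is survey records
#'   (e.g. `missing_policy`).
#' @return A data frame of class `adoption_series` with columns `year`
#'   (unique, ascending) and `fraction` (in `[0, 1]`).
#' @export
adoption_series <- function(x, ...) {
  if (inherits(x, "survey_records")) {
    years <- sort(unique(x$survey_year))
    tables <- lapply(years, function(y) tabulate_adoption(x, y, ...))
    return(adoption_series(tables))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("year", "fraction") %in% names(x)))
    return(new_adoption_series(x$year, x$fraction))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "adoption_table")))
  years <- vapply(x, function(tb) tb$survey_year, integer(1))
  fractions <- vapply(x, function(tb) unname(tb$counts["both_yes"] / tb$total),
                      numeric(1))
  new_adoption_series(years, fractions)
}

new_adoption_series <- function(year, fraction) {
  if (anyDuplicated(year)) {
    stop("duplicate survey years in adoption series: ",
         paste(unique(year[duplicated(year)]), collapse = ", "))
  }
  if (any(fraction < 0 | fraction > 1)) {
    stop("adoption fractions must lie in [0, 1]")
  }
  o <- order(year)
  out <- data.frame(year = as.integer(year[o]), fraction = fraction[o])
  class(out) <- c("adoption_series", "data.frame")
  out
}

#' Read a year/fraction adoption or policy-target series from CSV
#'
#' @param path CSV with header columns `year,fraction`.
#' @return An `adoption_series` data frame.
#' @export
read_adoption_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("year", "fraction") %in% names(df))) {
    stop("series CSV must have columns `year` and `fraction`")
  }
  new_adoption_series(df$year, df$fraction)
}
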