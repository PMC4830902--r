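# Shared fixtures: the published weighted joint-category counts for the
# three survey rounds, and builders that turn them into respondent-level
# records (one synthetic respondent per category, weight = weighted count).

hints_counts <- function() {
  data.frame(
    survey_year = rep(c(2008L, 2011L, 2013L), each = 4),
    category = rep(c("both_yes", "comm_only", "track_only", "both_no"), 3),
    weighted_count = c(
      7878118, 12881980, 13897188, 117944796,
      15407840, 14665440, 14761217, 112444964,
      31220465, 22880580, 19969109, 107794014
    )
  )
}

# published percentages (2 dp) in the same row order as hints_counts()
hints_percent <- function() {
  c(5.16, 8.44, 9.11, 77.29,
    9.80, 9.32, 9.39, 71.49,
    17.17, 12.58, 10.98, 59.27)
}

hints_records <- function() {
  cc <- hints_counts()
  track <- cc$category %in% c("both_yes", "track_only")
  comm <- cc$category %in% c("both_yes", "comm_only")
  survey_records(
    respondent_id = paste0("r", seq_len(nrow(cc))),
    survey_year = cc$survey_year,
    weight = cc$weighted_count,
    item_track = ifelse(track, "yes", "no"),
    item_comm = ifelse(comm, "yes", "no")
  )
}

# observed joint-use uptake series (fractions, 4 dp as published)
hints_series <- function() {
  adoption_series(data.frame(year = c(2008L, 2011L, 2013L),
                             fraction = c(0.0516, 0.0980, 0.1717)))
}

# write a small survey CSV and return its path
write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
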