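# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny 4-row count data frame with distinct stratum keys.
toy_counts_df <- function() {
  data.frame(area_id = c("a1", "a1", "a2", "a2"),
             sex = c("male", "female", "male", "female"),
             age_band = c("0-4", "0-4", "5-9", "5-9"),
             year = 2000L,
             events = c(3L, 1L, 0L, 2L))
}

toy_pop_df <- function() {
  df <- toy_counts_df()
  df$events <- NULL
  df$person_years <- c(1000, 1200, 800, 900)
  df
}

# Write a data frame as the canonical CSV layout (value column).
write_fixture_csv <- function(df, value_from) {
  path <- tempfile(fileext = ".csv")
  names(df)[names(df) == value_from] <- "value"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Single unit-square geography centred at the origin (coordinates in m).
unit_square_geo <- function(half = 0.5) {
  areaGeography("sq", list(rbind(c(-half, -half), c(half, -half),
                                 c(half, half), c(-half, half))))
}

# Independent brute-force oracle: distance from points to the nearest of a
# set of point sources, by direct evaluation.
brute_nearest_dist <- function(pts, source_xy) {
  apply(pts, 1, function(p)
    min(sqrt((source_xy[, 1] - p[1])^2 + (source_xy[, 2] - p[2])^2)))
}
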