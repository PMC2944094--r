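#' Default five-year age-band labels
#'
#' Eighteen five-year bands, \code{"0-4"} through \code{"80-84"} plus the
#' open-ended \code{"85+"}. The band structure is always user-declarable at
#' load time; this is merely the conventional default used by the synthetic
#' fixtures.
#'
#' @return Character vector of length 18.
#' @export
defaultAgeBands <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

# Columns that make up a stratum key, in canonical order.
.key_cols <- function(has_quintile) {
  c("area_id", "sex", "age_band", "year", if (has_quintile) "quintile")
}

.sex_levels <- c("male", "female")

# Collect validation problems for a stratum data frame. `lines` maps rows to
# source line numbers (for file input) so errors name the offending lines.
.validate_strata <- function(df, age_bands, value_col, lines = NULL,
                             integer_value = FALSE) {
  if (is.null(lines)) lines <- seq_len(nrow(df))
  probs <- character(0)
  bad_sex <- !(df$sex %in% .sex_levels)
  if (any(bad_sex)) {
    probs <- c(probs, sprintf(
      "line %d: sex '%s' is not 'male' or 'female'",
      lines[bad_sex], df$sex[bad_sex]))
  }
  bad_band <- !(df$age_band %in% age_bands)
  if (any(bad_band)) {
    probs <- c(probs, sprintf(
      "line %d: age band '%s' is not in the declared band list",
      lines[bad_band], df$age_band[bad_band]))
  }
  v <- df[[value_col]]
  bad_val <- !is.finite(v) | v < 0
  if (any(bad_val)) {
    probs <- c(probs, sprintf(
      "line %d: %s %s is negative or non-finite",
      lines[bad_val], value_col, format(v[bad_val])))
  }
  if (integer_value) {
    frac <- is.finite(v) & v >= 0 & v != round(v)
    if (any(frac)) {
      probs <- c(probs, sprintf(
        "line %d: %s %s is not an integer", lines[frac], value_col,
        format(v[frac])))
    }
  }
  if ("quintile" %in% names(df)) {
    bad_q <- !(df$quintile %in% 1:5)
    if (any(bad_q)) {
      probs <- c(probs, sprintf(
        "line %d: quintile %s is not in 1..5",
        lines[bad_q], format(df$quintile[bad_q])))
    }
  }
  key <- do.call(paste, c(df[.key_cols("quintile" %in% names(df))],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      at <- lines[key == k]
      probs <- c(probs, sprintf(
        "duplicate stratum key on lines %s", paste(at, collapse = ", ")))
    }
  }
  probs
}

.new_strat_table <- function(df, age_bands, value_col, class,
                             metadata = list()) {
  keys <- .key_cols("quintile" %in% names(df))
  df <- df[c(keys, value_col)]
  df$age_band <- factor(df$age_band, levels = age_bands)
  df$year <- as.integer(df$year)
  if ("quintile" %in% names(df)) df$quintile <- as.integer(df$quintile)
  rownames(df) <- NULL
  structure(df,
            age_bands = age_bands,
            metadata = metadata,
            class = c(class, "strat_table", "data.frame"))
}

#' Stratified event-count table
#'
#' A table of event counts per stratum (area, sex, age band, calendar year
#' and, optionally, a covariate quintile). Duplicate stratum keys, unknown
#' age bands and negative or fractional counts are rejected.
#'
#' @param df Data frame with columns \code{area_id}, \code{sex} (\code{male}/
#'   \code{female}), \code{age_band}, \code{year}, optionally
#'   \code{quintile} (1-5), and \code{events}.
#' @param age_bands Declared age-band labels, in order.
#' @param outcome Optional outcome label (e.g. \code{"NHL incidence"}).
#' @param codes Optional \code{\link{codeFilter}} describing the health codes
#'   the counts were extracted with.
#' @return An object of class \code{strat_counts} (a data frame).
#' @seealso \code{\link{readCounts}}, \code{\link{stratPopulation}}
#' @export
stratCounts <- function(df, age_bands = defaultAgeBands(), outcome = NULL,
                        codes = NULL) {
  stopifnot(is.data.frame(df))
  need <- c(.key_cols(FALSE), "events")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  probs <- .validate_strata(df, age_bands, "events", integer_value = TRUE)
  if (length(probs))
    stop("invalid count table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  df$events <- as.integer(round(df$events))
  .new_strat_table(df, age_bands, "events", "strat_counts",
                   metadata = list(outcome = outcome, codes = codes))
}

#' Stratified person-years table
#'
#' Person-years at risk per stratum, with the same key structure as
#' \code{\link{stratCounts}}. Person-years may be fractional but must be
#' non-negative.
#'
#' @inheritParams stratCounts
#' @param df Data frame with key columns plus \code{person_years}.
#' @return An object of class \code{strat_population}.
#' @export
stratPopulation <- function(df, age_bands = defaultAgeBands()) {
  stopifnot(is.data.frame(df))
  need <- c(.key_cols(FALSE), "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  probs <- .validate_strata(df, age_bands, "person_years")
  if (length(probs))
    stop("invalid population table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  .new_strat_table(df, age_bands, "person_years", "strat_population")
}

#' @export
print.strat_table <- function(x, ...) {
  kind <- if (inherits(x, "strat_counts")) "event counts" else "person-years"
  vcol <- if (inherits(x, "strat_counts")) "events" else "person_years"
  cat(sprintf("Stratified %s: %d cells, %d areas, total %s\n", kind,
              nrow(x), length(unique(x$area_id)),
              format(sum(x[[vcol]]))))
  cat(sprintf("  sexes: %s; age bands: %d declared; years: %s%s\n",
              paste(sort(unique(x$sex)), collapse = "/"),
              length(attr(x, "age_bands")),
              paste(range(x$year), collapse = "-"),
              if ("quintile" %in% names(x)) "; covariate quintiles present"
              else ""))
  invisible(x)
}

.read_table_file <- function(path, col_map) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(col_map)) {
    # col_map: c(internal_name = "file column name")
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw))
        stop("column '", col_map[[nm]], "' not found in ", path,
             call. = FALSE)
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  raw
}

#' Read a stratified count table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' \code{area_id}, \code{sex}, \code{age_band}, \code{year}, optionally
#' \code{quintile}, and \code{value} (the event count). Rows failing
#' validation are reported with their file line numbers (header is line 1).
#'
#' @param path Path to the CSV file.
#' @param age_bands Declared age-band labels.
#' @param col_map Optional named character vector mapping internal field
#'   names to file column names, e.g. \code{c(area_id = "ward", value = "n")}.
#' @param outcome,codes Passed to \code{\link{stratCounts}} metadata.
#' @return A \code{strat_counts} table.
#' @export
readCounts <- function(path, age_bands = defaultAgeBands(), col_map = NULL,
                       outcome = NULL, codes = NULL) {
  raw <- .read_table_file(path, col_map)
  if (!"value" %in% names(raw))
    stop("no 'value' column in ", path, call. = FALSE)
  names(raw)[names(raw) == "value"] <- "events"
  need <- c(.key_cols(FALSE), "events")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- .validate_strata(raw, age_bands, "events",
                            lines = seq_len(nrow(raw)) + 1L,
                            integer_value = TRUE)
  if (length(probs))
    stop("invalid rows in ", path, ":\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  raw$events <- as.integer(round(raw$events))
  .new_strat_table(raw, age_bands, "events", "strat_counts",
                   metadata = list(outcome = outcome, codes = codes))
}

#' Read a stratified person-years table from CSV
#'
#' Same layout as \code{\link{readCounts}}; the \code{value} column holds
#' person-years and may be fractional.
#'
#' @inheritParams readCounts
#' @return A \code{strat_population} table.
#' @export
readPopulation <- function(path, age_bands = defaultAgeBands(),
                           col_map = NULL) {
  raw <- .read_table_file(path, col_map)
  if (!"value" %in% names(raw))
    stop("no 'value' column in ", path, call. = FALSE)
  names(raw)[names(raw) == "value"] <- "person_years"
  need <- c(.key_cols(FALSE), "person_years")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- .validate_strata(raw, age_bands, "person_years",
                            lines = seq_len(nrow(raw)) + 1L)
  if (length(probs))
    stop("invalid rows in ", path, ":\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  .new_strat_table(raw, age_bands, "person_years", "strat_population")
}

#' Write a stratified table to CSV
#'
#' Writes the canonical CSV layout (\code{area_id, sex, age_band, year,
#' [quintile], value}) so that \code{\link{readCounts}} /
#' \code{\link{readPopulation}} round-trip cell values exactly.
#'
#' @param x A \code{strat_counts} or \code{strat_population} table.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(x, path) {
  stopifnot(inherits(x, "strat_table"))
  out <- as.data.frame(x)
  vcol <- if (inherits(x, "strat_counts")) "events" else "person_years"
  names(out)[names(out) == vcol] <- "value"
  out$age_band <- as.character(out$age_band)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total events or person-years in a stratified table
#'
#' @param x A \code{strat_table}.
#' @return Numeric total of the table's value column.
#' @export
tableTotal <- function(x) {
  stopifnot(inherits(x, "strat_table"))
  vcol <- if (inherits(x, "strat_counts")) "events" else "person_years"
  sum(x[[vcol]])
}
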