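#' Interpolate person-years between census years
#'
#' Decennial (or other periodic) census population tables are interpolated
#' cellwise and linearly to an intercensal target year, as is standard
#' practice when annual small-area denominators are unavailable. At a census
#' year the census table is returned exactly. Extrapolation beyond the first
#' or last census is refused unless explicitly allowed, in which case the
#' nearest census pair's linear slope is extended.
#'
#' @param tables List of \code{\link{stratPopulation}} tables, one per census;
#'   each must contain a single calendar year and all must share the same
#'   (area, sex, age band, quintile) stratum structure.
#' @param target_year Integer year to interpolate to.
#' @param allow_extrapolation Permit linear extension beyond the census hull?
#' @return A \code{strat_population} table with \code{year = target_year}.
#' @export
interpolatePopulation <- function(tables, target_year,
                                  allow_extrapolation = FALSE) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "strat_population")))
  years <- vapply(tables, function(t) {
    y <- unique(t$year)
    if (length(y) != 1L)
      stop("each census table must contain a single year", call. = FALSE)
    y
  }, integer(1))
  o <- order(years)
  years <- years[o]; tables <- tables[o]
  if (anyDuplicated(years))
    stop("duplicate census years supplied", call. = FALSE)

  has_q <- "quintile" %in% names(tables[[1]])
  keyof <- function(t) {
    do.call(paste, c(t[c("area_id", "sex", "age_band",
                         if (has_q) "quintile")], sep = "\r"))
  }
  ref_key <- keyof(tables[[1]])
  mats <- vapply(tables, function(t) {
    k <- keyof(t)
    if (length(k) != length(ref_key) || !setequal(k, ref_key) ||
        ("quintile" %in% names(t)) != has_q)
      stop("census tables have differing stratum structures", call. = FALSE)
    t$person_years[match(ref_key, k)]
  }, numeric(length(ref_key)))
  mats <- matrix(mats, nrow = length(ref_key))

  if (target_year %in% years) {
    i <- match(target_year, years)
    py <- mats[, i]
  } else if (target_year < years[1] || target_year > years[length(years)]) {
    if (!allow_extrapolation)
      stop("target year ", target_year, " lies outside the census hull [",
           years[1], ", ", years[length(years)],
           "]; set allow_extrapolation = TRUE to extend linearly",
           call. = FALSE)
    if (length(years) < 2L)
      stop("extrapolation needs at least two censuses", call. = FALSE)
    pair <- if (target_year < years[1]) c(1L, 2L)
            else c(length(years) - 1L, length(years))
    w <- (target_year - years[pair[1]]) / diff(years[pair])
    py <- pmax(0, (1 - w) * mats[, pair[1]] + w * mats[, pair[2]])
  } else {
    hi <- which(years > target_year)[1]
    lo <- hi - 1L
    w <- (target_year - years[lo]) / (years[hi] - years[lo])
    py <- (1 - w) * mats[, lo] + w * mats[, hi]
  }

  out <- tables[[1]][match(ref_key, keyof(tables[[1]])), , drop = FALSE]
  out$year <- as.integer(target_year)
  out$person_years <- py
  .new_strat_table(as.data.frame(out), attr(tables[[1]], "age_bands"),
                   "person_years", "strat_population")
}

#' Assign areas to covariate quintiles
#'
#' Quintile boundaries are the 20/40/60/80th percentiles of the area-level
#' value distribution. An area whose value falls exactly on a boundary is
#' assigned the lower quintile (documented tie rule; when all values are
#' equal every area lands in quintile 1).
#'
#' @param values Named numeric vector of area-level covariate values (names
#'   are area ids); at least 5 areas, all finite.
#' @return Named integer vector of quintiles 1-5.
#' @examples
#' assignQuintiles(setNames(1:10, paste0("a", 1:10)))
#' @export
assignQuintiles <- function(values) {
  if (length(values) < 5L)
    stop("need at least 5 areas to form quintiles", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite covariate values for areas: ",
         paste(names(values)[!is.finite(values)], collapse = ", "),
         call. = FALSE)
  br <- stats::quantile(values, c(.2, .4, .6, .8), names = FALSE, type = 7)
  q <- 1L + (values > br[1]) + (values > br[2]) + (values > br[3]) +
    (values > br[4])
  storage.mode(q) <- "integer"
  names(q) <- names(values)
  q
}
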