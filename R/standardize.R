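#' Stratum-specific reference rates
#'
#' Computes reference rates (events per person-year) per adjustment stratum
#' from a reference count and population table, or validates a precomputed
#' rate table. Strata are any subset of \code{sex}, \code{age_band},
#' \code{year}, \code{quintile}; the conventional choice is sex x age band,
#' with the covariate quintile added for socioeconomic adjustment. When the
#' study region is part of the reference region the whole-region rates
#' include the study area (as when a state is its own comparison
#' population); pass study tables to \code{exclude_counts} /
#' \code{exclude_pop} to remove the study area's contribution first.
#'
#' @param counts Reference \code{\link{stratCounts}} table, or a data frame
#'   with stratum columns plus \code{rate} to use precomputed rates.
#' @param pop Reference \code{\link{stratPopulation}} (ignored for
#'   precomputed rates).
#' @param strata Character vector of stratum columns the rates vary over.
#' @param exclude_counts,exclude_pop Optional study tables to subtract from
#'   the reference before forming rates.
#' @return A data frame of class \code{reference_rates} with the stratum
#'   columns and \code{rate}.
#' @export
referenceRates <- function(counts, pop = NULL,
                           strata = c("sex", "age_band"),
                           exclude_counts = NULL, exclude_pop = NULL) {
  if (is.data.frame(counts) && "rate" %in% names(counts) &&
      !inherits(counts, "strat_counts")) {
    if (!all(strata %in% names(counts)))
      stop("precomputed rate table lacks stratum columns: ",
           paste(setdiff(strata, names(counts)), collapse = ", "),
           call. = FALSE)
    if (any(counts$rate < 0)) stop("negative reference rate", call. = FALSE)
    out <- counts[c(strata, "rate")]
    class(out) <- c("reference_rates", "data.frame")
    attr(out, "strata") <- strata
    return(out)
  }
  stopifnot(inherits(counts, "strat_counts"),
            inherits(pop, "strat_population"))
  if (!is.null(exclude_counts)) {
    counts <- .subtract_table(counts, exclude_counts, "events")
    pop <- .subtract_table(pop, exclude_pop, "person_years")
  }
  ev <- stats::aggregate(counts["events"], counts[strata], sum, drop = TRUE)
  py <- stats::aggregate(pop["person_years"], pop[strata], sum, drop = TRUE)
  m <- merge(ev, py, by = strata, all = TRUE)
  m$events[is.na(m$events)] <- 0L
  if (anyNA(m$person_years) || any(m$person_years <= 0 & m$events > 0))
    stop("reference strata with events but no person-years", call. = FALSE)
  m$rate <- ifelse(m$person_years > 0, m$events / m$person_years, 0)
  out <- m[c(strata, "rate")]
  class(out) <- c("reference_rates", "data.frame")
  attr(out, "strata") <- strata
  out
}

.subtract_table <- function(big, small, vcol) {
  stopifnot(inherits(small, "strat_table"))
  has_q <- "quintile" %in% names(big)
  kb <- do.call(paste, c(big[.key_cols(has_q)], sep = "\r"))
  ks <- do.call(paste, c(small[.key_cols(has_q)], sep = "\r"))
  idx <- match(ks, kb)
  if (anyNA(idx))
    stop("study stratum not present in reference table", call. = FALSE)
  big[[vcol]][idx] <- big[[vcol]][idx] - small[[vcol]]
  if (any(big[[vcol]] < -1e-9))
    stop("study exceeds reference in some stratum", call. = FALSE)
  big[[vcol]] <- pmax(big[[vcol]], 0)
  big
}

#' Expected counts by indirect standardization
#'
#' Projects the reference population's stratum-specific rates onto the study
#' population's stratum structure:
#' \eqn{E = \sum_s n_s r_s}, with \eqn{n_s} the study person-years in
#' stratum s and \eqn{r_s} the reference rate. Expected counts are additive
#' over disjoint area sets, so band or region totals decompose exactly by
#' area.
#'
#' @param study_pop Study \code{\link{stratPopulation}}.
#' @param rates A \code{\link{referenceRates}} table.
#' @param by_area Return one E per area (default) or a single aggregate?
#' @return Named numeric vector of expected counts per area, or a scalar.
#' @export
expectedCount <- function(study_pop, rates, by_area = TRUE) {
  stopifnot(inherits(study_pop, "strat_population"),
            inherits(rates, "reference_rates"))
  strata <- attr(rates, "strata")
  miss_col <- setdiff(strata, names(study_pop))
  if (length(miss_col))
    stop("study population lacks stratum columns: ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  key_pop <- do.call(paste, c(lapply(study_pop[strata], as.character),
                              sep = "\r"))
  key_rate <- do.call(paste, c(lapply(rates[strata], as.character),
                               sep = "\r"))
  idx <- match(key_pop, key_rate)
  if (anyNA(idx)) {
    bad <- unique(key_pop[is.na(idx)])
    stop("no reference rate for study strata: ",
         paste(gsub("\r", "/", utils::head(bad, 5)), collapse = "; "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  contrib <- study_pop$person_years * rates$rate[idx]
  if (!by_area) return(sum(contrib))
  e <- tapply(contrib, study_pop$area_id, sum)
  out <- as.numeric(e)
  names(out) <- names(e)
  out
}

# Byar's cube-root approximation to the exact Poisson limits on a count,
# divided by E to give limits on the ratio.
.byar_ci <- function(O, E, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- if (O > 0) O * (1 - 1 / (9 * O) - z / (3 * sqrt(O)))^3 / E else 0
  up <- (O + 1) * (1 - 1 / (9 * (O + 1)) + z / (3 * sqrt(O + 1)))^3 / E
  c(lo, up)
}

# Exact Poisson limits via the chi-square inversion.
.exact_poisson_ci <- function(O, E, level) {
  a <- 1 - level
  lo <- if (O > 0) stats::qchisq(a / 2, 2 * O) / 2 / E else 0
  up <- stats::qchisq(1 - a / 2, 2 * (O + 1)) / 2 / E
  c(lo, up)
}

#' Indirectly standardized ratio (SIR/SMR) with confidence interval
#'
#' The ratio of observed to expected events, with a confidence interval from
#' Byar's cube-root approximation to the exact Poisson limits (the default,
#' accurate to the printed precision of routine reports even at small
#' counts) or from the exact chi-square inversion. With \code{O = 0} the
#' ratio and lower limit are 0 and the upper limit is the exact zero-count
#' bound.
#'
#' @param O Observed event count (non-negative integer).
#' @param E Expected events under the reference rates (> 0).
#' @param level Confidence level, default 0.95.
#' @param method \code{"byar"} or \code{"exact_poisson"}.
#' @param kind Label only: \code{"SIR"} (incidence) or \code{"SMR"}
#'   (mortality).
#' @param adjustment Optional character vector recording the strata adjusted
#'   for.
#' @return An object of class \code{standardized_result} with elements
#'   \code{observed}, \code{expected}, \code{ratio}, \code{ci},
#'   \code{level}, \code{method}, \code{kind}, \code{adjustment}.
#' @examples
#' indirectRatio(87, 120.92)   # ratio 0.72, 95% CI (0.58, 0.89)
#' @export
indirectRatio <- function(O, E, level = 0.95,
                          method = c("byar", "exact_poisson"),
                          kind = c("SIR", "SMR"), adjustment = NULL) {
  method <- match.arg(method)
  kind <- match.arg(kind)
  if (!is.finite(E) || E <= 0) stop("expected count must be positive",
                                    call. = FALSE)
  if (!is.finite(O) || O < 0 || O != round(O))
    stop("observed count must be a non-negative integer", call. = FALSE)
  ci <- switch(method,
               byar = .byar_ci(O, E, level),
               exact_poisson = .exact_poisson_ci(O, E, level))
  structure(list(observed = as.integer(O), expected = E, ratio = O / E,
                 ci = ci, level = level, method = method, kind = kind,
                 adjustment = adjustment),
            class = "standardized_result")
}

#' @export
print.standardized_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s: O = %d, E = %s, ratio = %s (%d%% CI %s-%s, %s)\n",
              x$kind, x$observed, format(round(x$expected, digits)),
              format(round(x$ratio, digits)), round(100 * x$level),
              format(round(x$ci[1], digits)),
              format(round(x$ci[2], digits)), x$method))
  if (!is.null(x$adjustment))
    cat("  adjusted for:", paste(x$adjustment, collapse = ", "), "\n")
  invisible(x)
}

#' Directly standardized rate with gamma confidence interval
#'
#' Applies the study population's stratum-specific rates to a standard
#' population's stratum weights: rate \eqn{= per \times \sum_s w_s o_s/n_s}
#' with \eqn{w_s} the standard population's share of stratum s. The
#' confidence interval uses the gamma method of Fay and Feuer on the
#' weighted Poisson sum, the standard approach for directly age-adjusted
#' rates.
#'
#' @param study_counts Study \code{\link{stratCounts}}.
#' @param study_pop Study \code{\link{stratPopulation}}.
#' @param standard_pop Data frame with the stratum columns and a
#'   \code{weight} column (person-years or shares of the standard
#'   population; normalized internally), or a \code{strat_population} whose
#'   person-years act as weights.
#' @param strata Stratum columns the rates vary over.
#' @param per Scale of the reported rate (default per 100,000 person-years).
#' @param level Confidence level.
#' @param label Label for the standard population.
#' @return An object of class \code{direct_rate_result} with \code{rate},
#'   \code{ci}, \code{per}, \code{observed}, \code{standard}.
#' @export
directRate <- function(study_counts, study_pop, standard_pop,
                       strata = c("sex", "age_band"), per = 1e5,
                       level = 0.95, label = "standard") {
  stopifnot(inherits(study_counts, "strat_counts"),
            inherits(study_pop, "strat_population"))
  if (inherits(standard_pop, "strat_population")) {
    standard_pop <- stats::aggregate(
      list(weight = standard_pop$person_years),
      lapply(standard_pop[strata], as.character), sum)
  }
  stopifnot(is.data.frame(standard_pop), "weight" %in% names(standard_pop))
  ev <- stats::aggregate(study_counts["events"],
                         lapply(study_counts[strata], as.character), sum)
  py <- stats::aggregate(study_pop["person_years"],
                         lapply(study_pop[strata], as.character), sum)
  m <- merge(merge(ev, py, by = strata, all = TRUE), standard_pop,
             by = strata, all.x = TRUE)
  m$events[is.na(m$events)] <- 0L
  if (anyNA(m$weight))
    stop("standard population lacks weights for some study strata",
         call. = FALSE)
  if (any(m$events > 0 & (is.na(m$person_years) | m$person_years <= 0)))
    stop("stratum with events but zero person-years", call. = FALSE)
  m <- m[m$person_years > 0, , drop = FALSE]
  w <- m$weight / sum(m$weight)
  x <- sum(w * m$events / m$person_years)
  v <- sum(w^2 * m$events / m$person_years^2)
  wmax <- max(w / m$person_years)
  a <- 1 - level
  lo <- if (x > 0) v / x * stats::qgamma(a / 2, x^2 / v) else 0
  up <- (v + wmax^2) / (x + wmax) *
    stats::qgamma(1 - a / 2, (x + wmax)^2 / (v + wmax^2))
  structure(list(rate = per * x, ci = per * c(lo, up), per = per,
                 observed = sum(m$events), standard = label,
                 level = level),
            class = "direct_rate_result")
}

#' @export
print.direct_rate_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Directly standardized rate: %s per %s person-years (%d%% CI %s-%s), standard: %s\n",
    format(round(x$rate, digits)), format(x$per, big.mark = ","),
    round(100 * x$level), format(round(x$ci[1], digits)),
    format(round(x$ci[2], digits)), x$standard))
  invisible(x)
}

#' Carstairs-style deprivation index
#'
#' Area deprivation score combining male unemployment, lack of car access,
#' low social class and household overcrowding: the sum of the four
#' components' z-scores across areas (unweighted area-level mean and SD, the
#' index's conventional construction). Larger values indicate more
#' deprivation; quintiles for adjustment are then formed with
#' \code{\link{assignQuintiles}}. A component with zero variance across
#' areas carries no information and is dropped with a warning.
#'
#' @param inputs Data frame with columns \code{area_id},
#'   \code{male_unemployment}, \code{no_car_access},
#'   \code{low_social_class}, \code{overcrowding}, each a proportion in
#'   [0, 1].
#' @return Named numeric vector of index values per area.
#' @export
carstairsIndex <- function(inputs) {
  comp <- c("male_unemployment", "no_car_access", "low_social_class",
            "overcrowding")
  stopifnot(is.data.frame(inputs), all(c("area_id", comp) %in% names(inputs)))
  if (nrow(inputs) < 2) stop("need at least 2 areas", call. = FALSE)
  for (v in comp) {
    x <- inputs[[v]]
    if (any(!is.finite(x) | x < 0 | x > 1))
      stop("component '", v, "' must be a proportion in [0, 1]",
           call. = FALSE)
  }
  z <- matrix(0, nrow(inputs), 0)
  for (v in comp) {
    s <- stats::sd(inputs[[v]])
    if (s == 0) {
      warning("component '", v, "' has zero variance across areas; dropped",
              call. = FALSE)
      next
    }
    z <- cbind(z, (inputs[[v]] - mean(inputs[[v]])) / s)
  }
  if (ncol(z) == 0)
    stop("all components have zero variance", call. = FALSE)
  idx <- rowSums(z)
  names(idx) <- as.character(inputs$area_id)
  idx
}
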