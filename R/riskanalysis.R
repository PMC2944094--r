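#' Band-level risk table
#'
#' Aggregates observed and expected counts over the member areas of each
#' distance band and computes the per-band standardized ratio with its
#' confidence interval, plus the overall ratio
#' \eqn{\hat\theta = \sum O / \sum E}. Bands with zero expected count are
#' flagged as unusable and are excluded from the homogeneity and trend
#' tests.
#'
#' @param membership Named integer vector (area id -> band index, \code{NA}
#'   = unassigned), as returned by \code{\link{selectAreas}}.
#' @param counts Study \code{\link{stratCounts}}.
#' @param pop Study \code{\link{stratPopulation}}.
#' @param rates \code{\link{referenceRates}} for the expected counts.
#' @param level,method Passed to \code{\link{indirectRatio}}.
#' @return An object of class \code{band_risk_table}: a data frame with one
#'   row per band (\code{band, n_areas, observed, expected, ratio, ci_lower,
#'   ci_upper, usable}) and attributes \code{overall} (the pooled
#'   \code{standardized_result}) and \code{level}.
#' @export
bandRisks <- function(membership, counts, pop, rates, level = 0.95,
                      method = c("byar", "exact_poisson")) {
  method <- match.arg(method)
  if (!length(membership) || all(is.na(membership)))
    stop("empty band membership", call. = FALSE)
  used <- names(membership)[!is.na(membership)]
  ka <- sort(unique(membership[!is.na(membership)]))
  K <- max(ka)
  E_area <- expectedCount(pop[pop$area_id %in% used, , drop = FALSE], rates)
  O_area <- tapply(counts$events[counts$area_id %in% used],
                   counts$area_id[counts$area_id %in% used], sum)
  rows <- lapply(seq_len(K), function(k) {
    ids <- names(membership)[!is.na(membership) & membership == k]
    O <- sum(O_area[names(O_area) %in% ids])
    E <- sum(E_area[names(E_area) %in% ids])
    usable <- is.finite(E) && E > 0
    if (usable) {
      r <- indirectRatio(O, E, level = level, method = method)
      data.frame(band = k, n_areas = length(ids), observed = O,
                 expected = E, ratio = r$ratio, ci_lower = r$ci[1],
                 ci_upper = r$ci[2], usable = TRUE)
    } else {
      data.frame(band = k, n_areas = length(ids), observed = O,
                 expected = E, ratio = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, usable = FALSE)
    }
  })
  tbl <- do.call(rbind, rows)
  if (!any(tbl$usable))
    stop("no band has positive expected count", call. = FALSE)
  if (any(!tbl$usable))
    warning("bands with zero expected count excluded from tests: ",
            paste(tbl$band[!tbl$usable], collapse = ", "), call. = FALSE)
  overall <- indirectRatio(sum(tbl$observed[tbl$usable]),
                           sum(tbl$expected[tbl$usable]),
                           level = level, method = method)
  structure(tbl, overall = overall, level = level,
            class = c("band_risk_table", "data.frame"))
}

#' @export
print.band_risk_table <- function(x, digits = 2, ...) {
  cat("Distance-band risk table\n")
  df <- as.data.frame(x)
  df$expected <- round(df$expected, digits)
  df$ratio <- round(df$ratio, digits)
  df$ci_lower <- round(df$ci_lower, digits)
  df$ci_upper <- round(df$ci_upper, digits)
  print(df, row.names = FALSE)
  ov <- attr(x, "overall")
  cat(sprintf("Overall: O = %d, E = %s, ratio = %s\n", ov$observed,
              format(round(ov$expected, digits)),
              format(round(ov$ratio, digits))))
  invisible(x)
}

.band_test_result <- function(statistic, df, p, label) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 label = label),
            class = "band_test")
}

#' @export
print.band_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$label, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Homogeneity test of risk across distance bands
#'
#' Chi-square test of whether the band-specific ratios share a common value,
#' conditional on the observed overall ratio
#' \eqn{\hat\theta = \sum O_k / \sum E_k}:
#' \deqn{X^2 = \sum_k (O_k - \hat\theta E_k)^2 / (\hat\theta E_k),}
#' on K - 1 degrees of freedom. This is the standard SMR heterogeneity
#' statistic; no continuity correction is applied.
#'
#' @param O Per-band observed counts (length K >= 2).
#' @param E Per-band expected counts, all positive.
#' @return A \code{band_test} with the statistic, df and upper-tail
#'   chi-square p-value.
#' @export
homogeneityTest <- function(O, E) {
  if (length(O) < 2 || length(E) != length(O))
    stop("need K >= 2 bands with matching O and E", call. = FALSE)
  if (any(!is.finite(E) | E <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  theta <- sum(O) / sum(E)
  x2 <- sum((O - theta * E)^2 / (theta * E))
  K <- length(O)
  .band_test_result(x2, K - 1L, stats::pchisq(x2, K - 1L,
                                              lower.tail = FALSE),
                    "homogeneity (chi-square)")
}

#' Linear trend test across distance bands
#'
#' Poisson score test of zero slope in the log-linear model
#' \eqn{O_k \sim Poisson(E_k e^{\beta_0 + \beta_1 x_k})}, conditional on the
#' overall ratio \eqn{\hat\theta}:
#' \deqn{U = \sum x_k O_k - \hat\theta \sum x_k E_k, \quad
#'       V = \hat\theta\left[\sum x_k^2 E_k -
#'       (\sum x_k E_k)^2 / \sum E_k\right],}
#' with \eqn{z = U/\sqrt{V}} referred to the standard normal (two-sided).
#' With K = 2 bands, \eqn{z^2} equals the homogeneity chi-square (score-test
#' equivalence). Default band scores are the ring midpoint distances in km;
#' band rank is a common alternative.
#'
#' @param O,E Per-band observed and expected counts.
#' @param scores Per-band numeric scores, not all equal.
#' @return A \code{band_test} with the z statistic and two-sided p-value.
#' @export
trendTest <- function(O, E, scores) {
  if (length(O) < 2 || length(E) != length(O) ||
      length(scores) != length(O))
    stop("need K >= 2 bands with matching O, E and scores", call. = FALSE)
  if (any(!is.finite(E) | E <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  if (length(unique(scores)) < 2)
    stop("degenerate scores (all equal)", call. = FALSE)
  theta <- sum(O) / sum(E)
  U <- sum(scores * O) - theta * sum(scores * E)
  V <- theta * (sum(scores^2 * E) - sum(scores * E)^2 / sum(E))
  if (V <= 0) stop("degenerate score variance", call. = FALSE)
  z <- U / sqrt(V)
  .band_test_result(z, NA_integer_, 2 * stats::pnorm(-abs(z)),
                    "linear trend (Poisson score z)")
}

#' Band midpoint scores in kilometers
#'
#' The default score vector for \code{\link{trendTest}}: the midpoint of
#' each ring's distance interval, in km.
#'
#' @param bands A \code{\link{buildBands}} result or a
#'   \code{\link{bandScheme}}.
#' @return Numeric vector of length K.
#' @export
bandMidpoints <- function(bands) {
  br <- if (inherits(bands, "band_set")) bands$breaks else bands$breaks
  lims <- c(0, br)
  (lims[-length(lims)] + lims[-1]) / 2 / 1000
}

#' Run both band tests on a band risk table
#'
#' Convenience wrapper applying \code{\link{homogeneityTest}} and
#' \code{\link{trendTest}} to the usable rows of a
#' \code{\link{bandRisks}} table.
#'
#' @param tbl A \code{band_risk_table}.
#' @param scores Per-band scores (matching all bands of the table); default
#'   band rank.
#' @return List with elements \code{homogeneity} and \code{trend}.
#' @export
bandTests <- function(tbl, scores = seq_len(nrow(tbl))) {
  stopifnot(inherits(tbl, "band_risk_table"))
  u <- tbl$usable
  list(homogeneity = homogeneityTest(tbl$observed[u], tbl$expected[u]),
       trend = trendTest(tbl$observed[u], tbl$expected[u], scores[u]))
}
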