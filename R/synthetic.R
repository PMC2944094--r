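#' Square-lattice study geography
#'
#' An n x n lattice of square areas with \code{cell_size_m} meter sides,
#' queen adjacency, and centroids at the cell centres. The workhorse
#' geography for simulation studies: it exercises the full geography,
#' adjacency and band machinery without any external data.
#'
#' @param n Lattice side (>= 2).
#' @param cell_size_m Cell edge length in meters.
#' @return List with elements \code{geography}
#'   (\code{\link{areaGeography}}, area ids \code{"gRxCy"} by row/column)
#'   and \code{adjacency} (queen).
#' @export
makeLattice <- function(n, cell_size_m = 1000) {
  if (n < 2) stop("lattice side must be at least 2", call. = FALSE)
  ids <- character(n * n)
  polys <- vector("list", n * n)
  k <- 0L
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      k <- k + 1L
      ids[k] <- sprintf("g%02dx%02d", r, c)
      x0 <- (c - 1) * cell_size_m; y0 <- (r - 1) * cell_size_m
      polys[[k]] <- rbind(c(x0, y0), c(x0 + cell_size_m, y0),
                          c(x0 + cell_size_m, y0 + cell_size_m),
                          c(x0, y0 + cell_size_m))
    }
  }
  geo <- areaGeography(ids, polys, crs = "lattice-meters")
  list(geography = geo, adjacency = buildAdjacency(geo, "queen"))
}

#' Relative-risk surface specifications
#'
#' Constructors for the truth surfaces understood by
#' \code{\link{simulateCounts}}:
#' \describe{
#'   \item{rrConstant}{the same relative risk everywhere.}
#'   \item{rrBanded}{step risks by distance band around sources; areas
#'     beyond the outermost break take \code{outside}.}
#'   \item{rrBlock}{a rectangular block of areas (by area id) at an
#'     anomalous risk, the rest at 1.}
#'   \item{rrIcarField}{a spatially correlated log-risk surface drawn from
#'     an ICAR with the stated precision, exponentiated and mean-normalized
#'     to 1 — a gentle spatially autocorrelated truth that separates
#'     local-mean from global-mean smoothing.}
#' }
#'
#' @param rr,rr_by_band,outside Relative-risk values.
#' @param bands A \code{\link{buildBands}} result (rrBanded).
#' @param area_ids Area ids forming the block (rrBlock).
#' @param precision ICAR precision of the log-risk field (rrIcarField).
#' @return An \code{rr_surface} specification.
#' @name rrSurfaces
NULL

#' @rdname rrSurfaces
#' @export
rrConstant <- function(rr = 1) {
  stopifnot(is.finite(rr), rr >= 0)
  structure(list(type = "constant", rr = rr), class = "rr_surface")
}

#' @rdname rrSurfaces
#' @export
rrBanded <- function(bands, rr_by_band, outside = 1) {
  stopifnot(inherits(bands, "band_set"),
            length(rr_by_band) == length(bands$breaks),
            all(rr_by_band >= 0), outside >= 0)
  structure(list(type = "banded", bands = bands, rr_by_band = rr_by_band,
                 outside = outside), class = "rr_surface")
}

#' @rdname rrSurfaces
#' @export
rrBlock <- function(area_ids, rr = 3) {
  stopifnot(length(area_ids) >= 1, is.finite(rr), rr >= 0)
  structure(list(type = "block", area_ids = as.character(area_ids),
                 rr = rr), class = "rr_surface")
}

#' @rdname rrSurfaces
#' @export
rrIcarField <- function(precision = 10) {
  stopifnot(is.finite(precision), precision > 0)
  structure(list(type = "icar", precision = precision),
            class = "rr_surface")
}

# Realize an rr_surface as a per-area vector (uses the current RNG state
# for the ICAR draw).
.realize_rr <- function(surface, geo, adjacency) {
  n <- length(geo$area_id)
  rr <- switch(surface$type,
    constant = rep(surface$rr, n),
    banded = {
      b <- selectAreas(geo, surface$bands)
      out <- rep(surface$outside, n)
      out[!is.na(b)] <- surface$rr_by_band[b[!is.na(b)]]
      out
    },
    block = {
      out <- rep(1, n)
      hit <- geo$area_id %in% surface$area_ids
      if (!any(hit)) stop("block area ids not found in geography",
                          call. = FALSE)
      out[hit] <- surface$rr
      out
    },
    icar = {
      if (is.null(adjacency))
        stop("ICAR surface needs an adjacency graph", call. = FALSE)
      W <- matrix(0, n, n)
      for (i in seq_len(n))
        if (length(adjacency$neighbours[[i]]))
          W[i, adjacency$neighbours[[i]]] <- 1
      L <- diag(rowSums(W)) - W
      ev <- eigen(L, symmetric = TRUE)
      pos <- ev$values > 1e-8 * max(ev$values)
      z <- stats::rnorm(sum(pos), 0,
                        1 / sqrt(surface$precision * ev$values[pos]))
      x <- as.vector(ev$vectors[, pos, drop = FALSE] %*% z)
      rr <- exp(x)
      rr / mean(rr)
    })
  names(rr) <- geo$area_id
  rr
}

#' Default log-linear baseline rates by age band
#'
#' Stratum baseline rates rising log-linearly with age, the shape typical of
#' adult cancer incidence: \code{rate0 * exp(slope * (band - 1))} per
#' person-year for age band 1..n_bands, with a small male excess.
#'
#' @param n_bands Number of age bands.
#' @param rate0 Rate in the youngest band (per person-year).
#' @param slope Log-rate increment per band.
#' @param male_excess Multiplier applied to male rates.
#' @return Data frame with \code{sex}, \code{age_band_index}, \code{rate}.
#' @export
baselineRates <- function(n_bands = 18, rate0 = 5e-6, slope = 0.25,
                          male_excess = 1.3) {
  grid <- expand.grid(sex = c("male", "female"),
                      age_band_index = seq_len(n_bands),
                      stringsAsFactors = FALSE)
  grid$rate <- rate0 * exp(slope * (grid$age_band_index - 1)) *
    ifelse(grid$sex == "male", male_excess, 1)
  grid
}

#' Simulate stratified Poisson counts over a geography
#'
#' Per stratum cell (area x sex x age band x year), events are drawn as
#' \eqn{Poisson(person\_years \times baseline\_rate \times RR_{area})}. The
#' baseline rates are returned as the reference-rate table, so expected
#' counts computed by \code{\link{expectedCount}} equal
#' \eqn{\sum person\_years \times rate} exactly and the per-area truth is
#' recoverable: \eqn{E[O_i] = E_i RR_i}. Person-years per cell are
#' log-normal across areas (small-area denominators are strongly skewed),
#' constant across strata within an area up to the age structure.
#' Deterministic under \code{seed}.
#'
#' @param geo An \code{\link{areaGeography}} (e.g. from
#'   \code{\link{makeLattice}}).
#' @param surface An \code{\link{rrSurfaces}} specification.
#' @param adjacency Adjacency (needed for ICAR surfaces).
#' @param n_age_bands Number of five-year age bands (uses the leading bands
#'   of \code{\link{defaultAgeBands}}).
#' @param years Calendar years covered (one cell per year).
#' @param rates Baseline rate table from \code{\link{baselineRates}}.
#' @param mean_py Median person-years per cell.
#' @param sd_log_py Log-scale SD of person-years across areas.
#' @param seed Integer seed (mandatory).
#' @return List with \code{counts} (\code{strat_counts}),
#'   \code{population} (\code{strat_population}), \code{reference_rates}
#'   (a \code{\link{referenceRates}} table over sex x age band), and
#'   \code{truth} (named per-area RR vector).
#' @export
simulateCounts <- function(geo, surface = rrConstant(1), adjacency = NULL,
                           n_age_bands = 18, years = 2001,
                           rates = baselineRates(n_age_bands),
                           mean_py = 300, sd_log_py = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(inherits(geo, "area_geography"),
            inherits(surface, "rr_surface"))
  set.seed(as.integer(seed))
  bands <- defaultAgeBands()[seq_len(n_age_bands)]
  n <- length(geo$area_id)

  truth <- .realize_rr(surface, geo, adjacency)

  grid <- expand.grid(area_id = geo$area_id, sex = c("male", "female"),
                      age_band = bands, year = as.integer(years),
                      stringsAsFactors = FALSE)
  # area-level size factor, shared across strata of an area
  size <- stats::rlnorm(n, log(mean_py), sd_log_py)
  names(size) <- geo$area_id
  grid$person_years <- size[grid$area_id] *
    stats::runif(nrow(grid), 0.8, 1.2)

  rate_key <- paste(rates$sex, rates$age_band_index)
  grid_key <- paste(grid$sex, match(grid$age_band, bands))
  grid$rate <- rates$rate[match(grid_key, rate_key)]
  lambda <- grid$person_years * grid$rate * truth[grid$area_id]
  grid$events <- stats::rpois(nrow(grid), lambda)

  counts <- stratCounts(grid[c("area_id", "sex", "age_band", "year",
                               "events")],
                        age_bands = bands, outcome = "synthetic")
  popn <- stratPopulation(grid[c("area_id", "sex", "age_band", "year",
                                 "person_years")], age_bands = bands)
  ref <- data.frame(sex = rates$sex,
                    age_band = bands[rates$age_band_index],
                    rate = rates$rate)
  ref <- referenceRates(ref, strata = c("sex", "age_band"))
  list(counts = counts, population = popn, reference_rates = ref,
       truth = truth)
}
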