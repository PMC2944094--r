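#' Distance-band scheme
#'
#' Ordered, strictly increasing distance breaks in meters defining half-open
#' annular rings around the sources: band k is
#' \eqn{\{x : d_{k-1} \le dist(x) < d_k\}} with \eqn{d_0 = 0}. A location
#' exactly at a break belongs to the outer band (half-open convention,
#' documented since boundary ties must resolve deterministically).
#'
#' @param breaks Numeric vector of distance breaks in meters, strictly
#'   increasing, all positive.
#' @return An object of class \code{band_scheme}.
#' @examples
#' bandScheme(c(2500, 5000))  # 0-2.5 km and 2.5-5 km rings
#' @export
bandScheme <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (!length(breaks) || any(!is.finite(breaks)) || any(breaks <= 0))
    stop("breaks must be positive and finite", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing", call. = FALSE)
  structure(list(breaks = breaks), class = "band_scheme")
}

#' Build distance bands around one or more sources
#'
#' With multiple sources the distance at any location is the distance to the
#' nearest source, so band regions are unions of buffer rings minus inner
#' buffers and are pairwise disjoint by construction.
#'
#' @param sources A single \code{\link{sourceGeometry}} or a list of them
#'   (non-empty, all in the geography's CRS).
#' @param scheme A \code{\link{bandScheme}}.
#' @return An object of class \code{band_set}.
#' @export
buildBands <- function(sources, scheme) {
  if (inherits(sources, "source_geometry")) sources <- list(sources)
  if (!length(sources))
    stop("empty source set", call. = FALSE)
  if (!all(vapply(sources, inherits, TRUE, "source_geometry")))
    stop("sources must be sourceGeometry objects", call. = FALSE)
  if (!inherits(scheme, "band_scheme")) scheme <- bandScheme(scheme)
  structure(list(sources = sources, breaks = scheme$breaks),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d source(s), %d bands: %s m\n",
              length(x$sources), length(x$breaks),
              paste(c(0, x$breaks), collapse = " | ")))
  invisible(x)
}

#' Number of bands in a band set
#' @param bands A \code{\link{buildBands}} result.
#' @return Integer number of rings.
#' @export
nBands <- function(bands) length(bands$breaks)

#' Distance from points to the nearest source
#'
#' @param bands A \code{band_set} (or list of \code{sourceGeometry}).
#' @param points n x 2 matrix of planar coordinates.
#' @return Numeric vector of distances in meters.
#' @export
distanceToSources <- function(bands, points) {
  srcs <- if (inherits(bands, "band_set")) bands$sources else bands
  points <- matrix(as.numeric(points), ncol = 2)
  d <- rep(Inf, nrow(points))
  for (s in srcs) d <- pmin(d, .dist_to_source(points[, 1], points[, 2], s))
  d
}

#' Band index of points
#'
#' @param bands A \code{band_set}.
#' @param points n x 2 coordinate matrix.
#' @return Integer vector: band index (1 = innermost), or \code{NA} beyond
#'   the outermost break.
#' @export
bandOf <- function(bands, points) {
  d <- distanceToSources(bands, points)
  idx <- findInterval(d, c(0, bands$breaks))
  idx[idx > length(bands$breaks)] <- NA_integer_
  idx
}

#' Assign areas to distance bands by centroid
#'
#' Each area is assigned to the unique band containing its chosen centroid;
#' areas whose centroid lies beyond the outermost break are unassigned
#' (\code{NA}) and excluded from band analyses (they are retained for
#' mapping analyses). The assignment is a partition: no area can fall in two
#' bands because band membership is a function of a single centroid
#' distance.
#'
#' @param bands A \code{\link{buildBands}} result.
#' @param geo An \code{\link{areaGeography}}.
#' @param method Centroid used for selection: the polygon's geometric
#'   centroid, or the supplied population-weighted centroid.
#' @return Named integer vector (names = area ids) of band indices, with
#'   \code{NA} for unassigned areas.
#' @export
selectAreas <- function(geo, bands,
                        method = c("geometric_centroid",
                                   "population_weighted_centroid")) {
  stopifnot(inherits(geo, "area_geography"), inherits(bands, "band_set"))
  method <- match.arg(method)
  pts <- if (method == "geometric_centroid") geo$centroids
         else {
           if (is.null(geo$pop_centroids))
             stop("population-weighted centroids are not present in this ",
                  "geography", call. = FALSE)
           geo$pop_centroids
         }
  b <- bandOf(bands, pts)
  names(b) <- geo$area_id
  b
}

#' Write band regions to GeoJSON
#'
#' Renders each band as annular ring polygons (outer circle with the inner
#' circle as a hole) around every point source, discretised at \code{n_seg}
#' segments, for choropleth/overlay display. This export is a visualisation
#' aid for point sources; where sources overlap, per-source rings are
#' emitted side by side (band membership itself is always computed from the
#' nearest-source distance, not from these rendered polygons). Line and
#' polygon sources are not rendered.
#'
#' @param bands A \code{band_set} whose sources are all points.
#' @param path Output path.
#' @param n_seg Circle discretisation (vertices per ring).
#' @return \code{path}, invisibly.
#' @export
writeBandRegions <- function(bands, path, n_seg = 180) {
  stopifnot(inherits(bands, "band_set"))
  types <- vapply(bands$sources, `[[`, character(1), "type")
  if (!all(types == "point"))
    stop("band-region rendering is implemented for point sources only",
         call. = FALSE)
  circle <- function(cx, cy, r, reverse = FALSE) {
    th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
    if (reverse) th <- rev(th)
    m <- cbind(cx + r * cos(th), cy + r * sin(th))
    rbind(m, m[1, , drop = FALSE])
  }
  to_coords <- function(m) lapply(seq_len(nrow(m)), function(k) m[k, ])
  feats <- list()
  lims <- c(0, bands$breaks)
  for (k in seq_len(length(bands$breaks))) {
    for (si in seq_along(bands$sources)) {
      s <- bands$sources[[si]]
      rings <- list(to_coords(circle(s$coords[1, 1], s$coords[1, 2],
                                     lims[k + 1])))
      if (lims[k] > 0)
        rings <- c(rings, list(to_coords(circle(s$coords[1, 1],
                                                s$coords[1, 2], lims[k],
                                                reverse = TRUE))))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(band = k, lower_m = lims[k],
                          upper_m = lims[k + 1],
                          source = if (is.null(s$label)) si else s$label),
        geometry = list(type = "Polygon", coordinates = rings))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
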