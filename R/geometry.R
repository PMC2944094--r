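# Low-level planar geometry. All coordinates are planar with metric units;
# rings are n x 2 matrices, not repeating the closing vertex.

# Strip a repeated closing vertex and coerce to matrix.
.as_ring <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 2, nrow(m) >= 3)
  n <- nrow(m)
  if (isTRUE(all.equal(m[1, ], m[n, ], check.attributes = FALSE)))
    m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("degenerate ring", call. = FALSE)
  unname(m)
}

# Shoelace signed area and area centroid of one ring.
.ring_area_centroid <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(cr))))
    return(list(area = 0, centroid = colMeans(r)))
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}

# Area centroid of a polygon given as list(outer, hole1, ...). Holes are
# subtracted regardless of their winding direction.
.polygon_area_centroid <- function(rings) {
  rings <- lapply(rings, .as_ring)
  parts <- lapply(rings, .ring_area_centroid)
  sgn <- c(1, rep(-1, length(parts) - 1))
  a <- vapply(parts, `[[`, numeric(1), "area")
  a <- sgn * abs(a)
  tot <- sum(a)
  if (tot <= 0) stop("polygon with non-positive area", call. = FALSE)
  cen <- colSums(do.call(rbind, lapply(parts, `[[`, "centroid")) * a) / tot
  list(area = tot, centroid = cen)
}

# Even-odd (ray crossing) point-in-polygon over all rings, so holes are
# handled naturally. px, py vectors.
.point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    r <- .as_ring(r)
    x <- r[, 1]; y <- r[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    for (k in seq_along(x)) {
      crosses <- ((y[k] > py) != (yn[k] > py)) &
        (px < (xn[k] - x[k]) * (py - y[k]) / (yn[k] - y[k]) + x[k])
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# Distance from points (px, py) to segment (ax,ay)-(bx,by); vectorised over
# the points.
.point_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# Distance from points to the boundary segments of a ring/linestring.
# closed = TRUE appends the closing segment.
.point_path_dist <- function(px, py, path, closed) {
  path <- as.matrix(path)
  n <- nrow(path)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  d <- rep(Inf, length(px))
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    d <- pmin(d, .point_seg_dist(px, py, path[i, 1], path[i, 2],
                                 path[j, 1], path[j, 2]))
  }
  d
}

#' Construct a source geometry
#'
#' A putative pollution source: a point, a set of points, a polyline or a
#' polygon, in the same planar metric coordinate system as the study
#' geography. Distance from a location to a polygon source is zero inside
#' the polygon.
#'
#' @param type One of \code{"point"}, \code{"multipoint"},
#'   \code{"linestring"}, \code{"polygon"}.
#' @param coords For \code{point}, \code{c(x, y)}; for \code{multipoint} and
#'   \code{linestring}, an n x 2 matrix; for \code{polygon}, a list of rings
#'   (outer first), each an n x 2 matrix.
#' @param label Optional source label.
#' @return An object of class \code{source_geometry}.
#' @export
sourceGeometry <- function(type = c("point", "multipoint", "linestring",
                                    "polygon"),
                           coords, label = NULL) {
  type <- match.arg(type)
  coords <- switch(type,
    point = {
      v <- as.numeric(coords)
      stopifnot(length(v) == 2, all(is.finite(v)))
      matrix(v, 1)
    },
    multipoint = ,
    linestring = {
      m <- as.matrix(coords)
      stopifnot(ncol(m) == 2, nrow(m) >= 1, all(is.finite(m)))
      m
    },
    polygon = {
      if (is.matrix(coords)) coords <- list(coords)
      lapply(coords, .as_ring)
    })
  structure(list(type = type, coords = coords, label = label),
            class = "source_geometry")
}

# Distance from points to one source geometry.
.dist_to_source <- function(px, py, src) {
  switch(src$type,
    point = sqrt((px - src$coords[1, 1])^2 + (py - src$coords[1, 2])^2),
    multipoint = {
      d <- rep(Inf, length(px))
      for (i in seq_len(nrow(src$coords)))
        d <- pmin(d, sqrt((px - src$coords[i, 1])^2 +
                            (py - src$coords[i, 2])^2))
      d
    },
    linestring = .point_path_dist(px, py, src$coords, closed = FALSE),
    polygon = {
      d <- rep(Inf, length(px))
      for (r in src$coords)
        d <- pmin(d, .point_path_dist(px, py, r, closed = TRUE))
      d[.point_in_rings(px, py, src$coords)] <- 0
      d
    })
}

#' Project longitude/latitude to a local planar metric system
#'
#' Simple local equirectangular projection about a stated origin: x =
#' R cos(lat0) (lon - lon0), y = R (lat - lat0), with R the mean Earth
#' radius (6371008.8 m). Adequate for study regions up to a few hundred
#' kilometres across, which is the intended scale; it is provided so that
#' geographic-coordinate input can be used after an explicit projection
#' step, since buffering and distance in degrees are meaningless.
#'
#' @param lonlat n x 2 matrix of longitude, latitude in degrees.
#' @param origin \code{c(lon0, lat0)}; defaults to the centroid of the input.
#' @return n x 2 matrix of planar coordinates in meters.
#' @export
projectLonLat <- function(lonlat, origin = colMeans(lonlat)) {
  lonlat <- as.matrix(lonlat)
  R <- 6371008.8
  rad <- pi / 180
  cbind(R * cos(origin[2] * rad) * (lonlat[, 1] - origin[1]) * rad,
        R * (lonlat[, 2] - origin[2]) * rad)
}
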