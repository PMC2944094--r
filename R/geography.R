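#' Area geography: polygons, centroids, optional population-weighted centroids
#'
#' Holds one polygon (possibly with holes) per area in a planar metric
#' coordinate system, with geometric centroids recomputed from the polygon
#' boundary on construction. Population-weighted centroids are supplied as
#' data when available (they cannot be derived from boundaries alone);
#' geometric centroids are always computed.
#'
#' @param area_id Character vector of unique area identifiers.
#' @param polygons List (one element per area) of polygons; each polygon is
#'   a list of rings (outer ring first), each ring an n x 2 coordinate
#'   matrix. A bare matrix is taken as a single-ring polygon.
#' @param pop_centroids Optional n x 2 matrix of population-weighted
#'   centroids, rows in \code{area_id} order.
#' @param crs Free-text label of the planar metric CRS the coordinates are
#'   expressed in (e.g. an EPSG code); purely descriptive, but geographic
#'   (lon/lat) coordinates must be projected first — see
#'   \code{\link{projectLonLat}}.
#' @return An object of class \code{area_geography}.
#' @seealso \code{\link{readAreaGeography}}, \code{\link{buildAdjacency}}
#' @export
areaGeography <- function(area_id, polygons, pop_centroids = NULL,
                          crs = "planar-metric") {
  area_id <- as.character(area_id)
  if (anyDuplicated(area_id))
    stop("duplicate area ids: ",
         paste(unique(area_id[duplicated(area_id)]), collapse = ", "),
         call. = FALSE)
  stopifnot(length(polygons) == length(area_id))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(as.matrix(p))
    lapply(p, .as_ring)
  })
  cen <- t(vapply(polygons,
                  function(p) .polygon_area_centroid(p)$centroid,
                  numeric(2)))
  areas <- vapply(polygons, function(p) .polygon_area_centroid(p)$area,
                  numeric(1))
  dimnames(cen) <- list(area_id, c("x", "y"))
  if (!is.null(pop_centroids)) {
    pop_centroids <- as.matrix(pop_centroids)
    stopifnot(nrow(pop_centroids) == length(area_id),
              ncol(pop_centroids) == 2)
    dimnames(pop_centroids) <- list(area_id, c("x", "y"))
  }
  structure(list(area_id = area_id, polygons = polygons,
                 centroids = cen, pop_centroids = pop_centroids,
                 areas_m2 = areas, crs = crs),
            class = "area_geography")
}

#' @export
print.area_geography <- function(x, ...) {
  cat(sprintf("<area_geography> %d areas, CRS '%s'%s\n",
              length(x$area_id), x$crs,
              if (!is.null(x$pop_centroids))
                ", population-weighted centroids present" else ""))
  invisible(x)
}

#' Number of areas in a geography
#' @param geo An \code{\link{areaGeography}}.
#' @return Integer count.
#' @export
nAreas <- function(geo) length(geo$area_id)

.geojson_polygon_coords <- function(geom) {
  # returns list of polygons, each a list of ring matrices
  to_ring <- function(ring)
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  if (geom$type == "Polygon") {
    list(lapply(geom$coordinates, to_ring))
  } else if (geom$type == "MultiPolygon") {
    lapply(geom$coordinates, function(poly) lapply(poly, to_ring))
  } else {
    stop("unsupported geometry type for areas: ", geom$type, call. = FALSE)
  }
}

.looks_geographic <- function(polygons) {
  xy <- do.call(rbind, lapply(polygons, function(p) do.call(rbind, p)))
  all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)
}

#' Read an area geography from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features. For a
#' MultiPolygon the largest part carries the centroid computation (all parts
#' are kept for adjacency). Coordinates that look geographic (within
#' lon/lat bounds) are refused unless either \code{crs} declares a planar
#' system explicitly or \code{project = TRUE} applies
#' \code{\link{projectLonLat}} about the dataset centroid.
#'
#' @param path GeoJSON file path.
#' @param id_property Feature property holding the area id.
#' @param pop_centroid_properties Optional length-2 character vector naming
#'   the properties with population-weighted centroid x and y.
#' @param crs Declared CRS label; \code{NULL} means undeclared.
#' @param project Apply the local equirectangular projection to lon/lat
#'   input?
#' @return An \code{\link{areaGeography}}.
#' @export
readAreaGeography <- function(path, id_property = "area_id",
                              pop_centroid_properties = NULL, crs = NULL,
                              project = FALSE) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path,
                                 call. = FALSE)
  ids <- character(0); polys <- list(); pcs <- NULL
  if (!is.null(pop_centroid_properties))
    pcs <- matrix(NA_real_, length(gj$features), 2)
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature ", i, " lacks property '", id_property,
                          "'", call. = FALSE)
    parts <- .geojson_polygon_coords(f$geometry)
    # merge multipolygon parts: outer rings of every part + holes; centroid
    # computation below subtracts holes only within the first part, so for
    # multiparts we use all rings of all parts with the largest part first
    rings <- unlist(parts, recursive = FALSE)
    if (length(parts) > 1) {
      sizes <- vapply(parts, function(p)
        abs(.ring_area_centroid(.as_ring(p[[1]]))$area), numeric(1))
      ord <- order(sizes, decreasing = TRUE)
      rings <- unlist(parts[ord], recursive = FALSE)
    }
    ids <- c(ids, as.character(id))
    polys[[length(polys) + 1L]] <- rings
    if (!is.null(pcs)) {
      pcs[i, ] <- c(as.numeric(f$properties[[pop_centroid_properties[1]]]),
                    as.numeric(f$properties[[pop_centroid_properties[2]]]))
    }
  }
  if (.looks_geographic(polys) && is.null(crs) && !project)
    stop("coordinates look geographic (lon/lat); supply a planar `crs` ",
         "label or set project = TRUE", call. = FALSE)
  if (project) {
    xy <- do.call(rbind, lapply(polys, function(p) do.call(rbind, p)))
    origin <- colMeans(xy)
    polys <- lapply(polys, function(p)
      lapply(p, function(r) projectLonLat(r, origin)))
    if (!is.null(pcs)) pcs <- projectLonLat(pcs, origin)
    crs <- sprintf("local-equirectangular(%.5f,%.5f)", origin[1], origin[2])
  }
  areaGeography(ids, polys, pop_centroids = pcs,
                crs = if (is.null(crs)) "planar-metric" else crs)
}

#' Write areas (optionally annotated with results) to GeoJSON
#'
#' Emits one Polygon feature per area with the area id and any supplied
#' per-area properties, ready for choropleth rendering in a GIS.
#'
#' @param geo An \code{\link{areaGeography}}.
#' @param path Output path.
#' @param properties Optional data frame of per-area properties; matched to
#'   areas by a column \code{area_id} if present, else by row order.
#' @return \code{path}, invisibly.
#' @export
writeAreaGeoJSON <- function(geo, path, properties = NULL) {
  stopifnot(inherits(geo, "area_geography"))
  if (!is.null(properties)) {
    properties <- as.data.frame(properties)
    if ("area_id" %in% names(properties)) {
      properties <- properties[match(geo$area_id, properties$area_id), ,
                               drop = FALSE]
    } else if (nrow(properties) != length(geo$area_id)) {
      stop("properties must have an area_id column or one row per area",
           call. = FALSE)
    }
  }
  feats <- lapply(seq_along(geo$area_id), function(i) {
    rings <- lapply(geo$polygons[[i]], function(r)
      lapply(seq_len(nrow(r) + 1L), function(k) {
        kk <- if (k > nrow(r)) 1L else k
        c(r[kk, 1], r[kk, 2])
      }))
    props <- list(area_id = geo$area_id[i])
    if (!is.null(properties)) {
      for (nm in setdiff(names(properties), "area_id")) {
        v <- properties[[nm]][i]
        props[[nm]] <- if (is.factor(v)) as.character(v) else v
      }
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Build a contiguity adjacency graph from polygons
#'
#' Queen contiguity joins areas sharing any boundary vertex; rook contiguity
#' requires a shared edge of positive length. Vertices are snapped to a
#' tolerance grid before matching, so conforming polygon layers (shared
#' borders digitised with the same vertices, as in census geographies and
#' lattices) are handled exactly. The output is symmetric with no
#' self-loops; isolated areas are permitted but flagged.
#'
#' @param geo An \code{\link{areaGeography}}.
#' @param rule \code{"queen"} or \code{"rook"}.
#' @param snap Snapping tolerance in coordinate units (meters).
#' @return An object of class \code{adjacency}: neighbour index lists per
#'   area plus the area ids.
#' @export
buildAdjacency <- function(geo, rule = c("queen", "rook"), snap = 1e-6) {
  stopifnot(inherits(geo, "area_geography"))
  rule <- match.arg(rule)
  n <- length(geo$area_id)
  vkey <- function(m) paste(round(m[, 1] / snap), round(m[, 2] / snap))
  pairs <- new.env(parent = emptyenv())
  add <- function(key, i) {
    cur <- pairs[[key]]
    pairs[[key]] <- c(cur, i)
  }
  for (i in seq_len(n)) {
    for (r in geo$polygons[[i]]) {
      keys <- vkey(r)
      if (rule == "queen") {
        for (k in unique(keys)) add(k, i)
      } else {
        nk <- c(keys[-1], keys[1])
        ek <- ifelse(keys < nk, paste(keys, nk, sep = "|"),
                     paste(nk, keys, sep = "|"))
        for (k in unique(ek)) add(k, i)
      }
    }
  }
  nb <- vector("list", n)
  for (k in ls(pairs)) {
    hit <- unique(pairs[[k]])
    if (length(hit) > 1) {
      for (i in hit) nb[[i]] <- c(nb[[i]], setdiff(hit, i))
    }
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  iso <- vapply(nb, length, integer(1)) == 0L
  if (any(iso))
    warning("isolated areas (no ", rule, " neighbours): ",
            paste(geo$area_id[iso], collapse = ", "), call. = FALSE)
  structure(list(area_id = geo$area_id, neighbours = nb, rule = rule),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  deg <- vapply(x$neighbours, length, integer(1))
  cat(sprintf("<adjacency> %d areas (%s), %d links, %d isolated\n",
              length(x$area_id), x$rule, sum(deg) / 2, sum(deg == 0)))
  invisible(x)
}

#' Identify areas with no neighbours
#' @param adj An \code{\link{buildAdjacency}} result.
#' @return Character vector of isolated area ids.
#' @export
isolatedAreas <- function(adj) {
  adj$area_id[vapply(adj$neighbours, length, integer(1)) == 0L]
}

#' Write an adjacency graph as neighbour-list text
#'
#' One line per area: \code{area_id n_neighbours neighbour_ids...},
#' space-separated.
#'
#' @param adj An adjacency object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAdjacency <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  lines <- vapply(seq_along(adj$area_id), function(i) {
    nbs <- adj$area_id[adj$neighbours[[i]]]
    paste(c(adj$area_id[i], length(nbs), nbs), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an adjacency graph from neighbour-list text
#'
#' @param path File written by \code{\link{writeAdjacency}}.
#' @return An \code{adjacency} object.
#' @export
readAdjacency <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(toks, `[[`, character(1), 1)
  nb_ids <- lapply(toks, function(t) {
    k <- as.integer(t[2])
    if (k > 0) t[2 + seq_len(k)] else character(0)
  })
  nb <- lapply(nb_ids, function(v) sort(match(v, ids)))
  if (anyNA(unlist(nb)))
    stop("neighbour id not present as an area", call. = FALSE)
  adj <- structure(list(area_id = ids, neighbours = nb, rule = "file"),
                   class = "adjacency")
  .check_symmetric(adj)
  adj
}

.check_symmetric <- function(adj) {
  for (i in seq_along(adj$neighbours)) {
    for (j in adj$neighbours[[i]]) {
      if (j == i) stop("self-loop in adjacency at ", adj$area_id[i],
                       call. = FALSE)
      if (!(i %in% adj$neighbours[[j]]))
        stop("asymmetric adjacency: ", adj$area_id[i], " -> ",
             adj$area_id[j], call. = FALSE)
    }
  }
  invisible(adj)
}

# igraph view of an adjacency object (internal).
.adj_igraph <- function(adj) {
  n <- length(adj$area_id)
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- adj$neighbours[[i]]
    js <- js[js > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  g
}
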