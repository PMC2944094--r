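test_that("geometric centroids are recomputed from the polygon boundary", {
  geo <- unit_square_geo()
  expect_equal(unname(geo$centroids[1, ]), c(0, 0))

  # L-shaped polygon: centroid from the shoelace formula, not the vertex mean
  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  geoL <- areaGeography("L", list(L))
  # oracle: decompose into two unit-height rectangles (2x1 at y 0-1,
  # 1x1 at y 1-2): centroid = (2*(1,0.5)+1*(0.5,1.5))/3
  expect_equal(unname(geoL$centroids[1, ]), c(2 * 1 + 0.5, 2 * 0.5 + 1.5) / 3)

  # a hole shifts the centroid away from the hole
  outer <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  hole <- rbind(c(2.5, 1.5), c(3.5, 1.5), c(3.5, 2.5), c(2.5, 2.5))
  geoH <- areaGeography("H", list(list(outer, hole)))
  expect_equal(unname(geoH$centroids[1, ]),
               c((16 * 2 - 1 * 3) / 15, (16 * 2 - 1 * 2) / 15))
})

test_that("queen and rook contiguity on a 3x3 lattice match lattice combinatorics", {
  lat <- makeLattice(3)
  queen <- lat$adjacency
  centre <- match("g02x02", queen$area_id)
  expect_equal(length(queen$neighbours[[centre]]), 8L)
  rook <- buildAdjacency(lat$geography, "rook")
  expect_equal(length(rook$neighbours[[centre]]), 4L)
  corner <- match("g01x01", rook$area_id)
  expect_equal(length(rook$neighbours[[corner]]), 2L)
  expect_equal(length(queen$neighbours[[corner]]), 3L)
})

test_that("adjacency is symmetric with no self-loops and round-trips through text", {
  lat <- makeLattice(4)
  adj <- lat$adjacency
  for (i in seq_along(adj$neighbours)) {
    expect_false(i %in% adj$neighbours[[i]])
    for (j in adj$neighbours[[i]]) expect_true(i %in% adj$neighbours[[j]])
  }
  path <- tempfile(fileext = ".txt")
  writeAdjacency(adj, path)
  back <- readAdjacency(path)
  expect_identical(back$neighbours, adj$neighbours)
  expect_identical(back$area_id, adj$area_id)
})

test_that("disjoint polygons are flagged isolated", {
  far <- areaGeography(c("p", "q"), list(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11))))
  expect_warning(adj <- buildAdjacency(far, "queen"), "isolated")
  expect_equal(isolatedAreas(adj), c("p", "q"))
})

test_that("band construction validates its inputs", {
  expect_error(bandScheme(c(5000, 2500)), "strictly increasing")
  expect_error(bandScheme(c(-1, 10)), "positive")
  expect_error(buildBands(list(), bandScheme(1000)), "empty source set")
})

test_that("with multiple sources, band membership follows the nearest source", {
  s1 <- sourceGeometry("point", c(0, 0))
  s2 <- sourceGeometry("point", c(10000, 0))
  bands <- buildBands(list(s1, s2), bandScheme(c(2500, 5000)))
  # probe grid oracle: direct distance evaluation per point
  set.seed(42)
  pts <- cbind(runif(400, -6000, 16000), runif(400, -6000, 6000))
  d_oracle <- brute_nearest_dist(pts, rbind(c(0, 0), c(10000, 0)))
  band_oracle <- ifelse(d_oracle < 2500, 1L,
                        ifelse(d_oracle < 5000, 2L, NA_integer_))
  expect_identical(bandOf(bands, pts), band_oracle)

  # a point in band 1 of one source and band 2 of the other takes band 1
  p <- matrix(c(1000, 0), 1)  # 1 km from s1, 9 km from s2
  expect_identical(bandOf(bands, p), 1L)

  # coincident duplicate sources change nothing
  bands_dup <- buildBands(list(s1, s1, s2), bandScheme(c(2500, 5000)))
  expect_identical(bandOf(bands_dup, pts), bandOf(bands, pts))
})

test_that("band regions partition by distance: disjoint and nested-complement consistent", {
  bands <- buildBands(sourceGeometry("point", c(0, 0)),
                      bandScheme(c(1000, 2000, 3000)))
  set.seed(7)
  pts <- cbind(runif(500, -3500, 3500), runif(500, -3500, 3500))
  b <- bandOf(bands, pts)
  d <- distanceToSources(bands, pts)
  # union of bands 1..k == distance <= d_k region (half-open rings)
  for (k in 1:3) {
    expect_identical(!is.na(b) & b <= k, d < bands$breaks[k])
  }
})

test_that("areas are selected by the chosen centroid with the half-open break convention", {
  geo <- unit_square_geo()
  bands <- buildBands(sourceGeometry("point", c(0, 0)),
                      bandScheme(2500))
  expect_identical(unname(selectAreas(geo, bands)), 1L)

  # centroid exactly at a break -> outer band
  geo2 <- areaGeography(c("in", "edge"), list(
    rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5)),
    rbind(c(999.5, -0.5), c(1000.5, -0.5), c(1000.5, 0.5), c(999.5, 0.5))))
  b2 <- buildBands(sourceGeometry("point", c(0, 0)),
                   bandScheme(c(1000, 5000)))
  sel <- selectAreas(geo2, b2)
  expect_identical(unname(sel), c(1L, 2L))

  # population-weighted centroids are used when requested, required if chosen
  geo3 <- areaGeography("a", list(rbind(c(-0.5, -0.5), c(0.5, -0.5),
                                        c(0.5, 0.5), c(-0.5, 0.5))),
                        pop_centroids = matrix(c(3000, 0), 1))
  expect_identical(unname(selectAreas(geo3, b2)), 1L)
  expect_identical(
    unname(selectAreas(geo3, b2, "population_weighted_centroid")), 2L)
  expect_error(selectAreas(geo, b2, "population_weighted_centroid"),
               "not present")
})

test_that("lattice band selection equals a brute-force per-centroid distance test", {
  lat <- makeLattice(10, 1)  # 10x10 lattice in unit cells
  bands <- buildBands(sourceGeometry("point", c(0, 0)),
                      bandScheme(c(2.5, 5)))
  sel <- selectAreas(lat$geography, bands)
  d <- brute_nearest_dist(lat$geography$centroids, rbind(c(0, 0)))
  oracle <- ifelse(d < 2.5, 1L, ifelse(d < 5, 2L, NA_integer_))
  expect_identical(unname(sel), unname(oracle))
})

test_that("line and polygon sources measure distance to the geometry, zero inside polygons", {
  line <- sourceGeometry("linestring", rbind(c(0, 0), c(1000, 0)))
  d <- distanceToSources(list(line),
                         rbind(c(500, 300), c(-300, 0), c(1400, 0)))
  expect_equal(d, c(300, 300, 400))

  poly <- sourceGeometry("polygon", rbind(c(0, 0), c(1000, 0),
                                          c(1000, 1000), c(0, 1000)))
  d2 <- distanceToSources(list(poly),
                          rbind(c(500, 500), c(1500, 500), c(500, -250)))
  expect_equal(d2, c(0, 500, 250))
})

test_that("GeoJSON areas round-trip with centroids intact and lon/lat input is refused without projection", {
  lat <- makeLattice(3, 1000)
  path <- tempfile(fileext = ".geojson")
  writeAreaGeoJSON(lat$geography, path,
                   properties = data.frame(area_id = lat$geography$area_id,
                                           score = seq_len(9)))
  back <- readAreaGeography(path, crs = "lattice-meters")
  expect_identical(back$area_id, lat$geography$area_id)
  expect_equal(back$centroids, lat$geography$centroids)

  # degree-valued coordinates must be projected explicitly
  ll <- areaGeography("d", list(rbind(c(0, 50), c(0.01, 50),
                                      c(0.01, 50.01), c(0, 50.01))))
  path2 <- tempfile(fileext = ".geojson")
  writeAreaGeoJSON(ll, path2)
  expect_error(readAreaGeography(path2), "geographic")
  proj <- readAreaGeography(path2, project = TRUE)
  # ~0.01 deg lat is ~1.11 km on the ground
  side <- diff(range(proj$polygons[[1]][[1]][, 2]))
  expect_true(abs(side - 1112) < 5)
})

test_that("band regions export as annuli for point sources", {
  bands <- buildBands(sourceGeometry("point", c(0, 0), label = "site"),
                      bandScheme(c(2500, 5000)))
  path <- tempfile(fileext = ".geojson")
  writeBandRegions(bands, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(length(gj$features), 2L)
  expect_equal(gj$features[[2]]$properties$lower_m, 2500)
  # outer band has an inner hole ring
  expect_equal(length(gj$features[[2]]$geometry$coordinates), 2L)
  line <- sourceGeometry("linestring", rbind(c(0, 0), c(1, 1)))
  expect_error(writeBandRegions(buildBands(line, bandScheme(100)),
                                tempfile()), "point sources")
})
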