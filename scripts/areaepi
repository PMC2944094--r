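#!/usr/bin/env Rscript
# Command-line front end: synth | bands | map. Thin wrappers over the
# exported functions; all analysis lives in the package.
#
#   areaepi synth --config spec.yaml --outdir DIR
#   areaepi bands --counts c.csv --pop p.csv --rates r.csv \
#                 --geography g.geojson --source X,Y --breaks 2500,5000 \
#                 --outdir DIR
#   areaepi map   --counts c.csv --pop p.csv --rates r.csv \
#                 --geography g.geojson --seed N --outdir DIR

suppressPackageStartupMessages({
  library(areaepi)
  library(optparse)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

usage <- function() {
  cat("usage: areaepi <synth|bands|map> [options]; see script header\n")
  quit(status = 2)
}

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) usage()
cmd <- argv[1]
rest <- argv[-1]

read_inputs <- function(o) {
  ab <- defaultAgeBands()[seq_len(o$age_bands)]
  list(counts = readCounts(o$counts, age_bands = ab),
       pop = readPopulation(o$pop, age_bands = ab),
       rates = referenceRates(read.csv(o$rates), strata = c("sex", "age_band")),
       geo = readAreaGeography(o$geography, crs = o$crs))
}

if (cmd == "synth") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"),
    make_option("--outdir", type = "character", default = "."))),
    args = rest)
  cfg <- yaml::read_yaml(o$config)
  if (is.null(cfg$seed)) stop("config must state a seed")
  lat <- makeLattice(cfg$lattice %||% 20, cfg$cell_size_m %||% 1000)
  surface <- switch(cfg$surface %||% "constant",
    constant = rrConstant(cfg$rr %||% 1),
    banded = rrBanded(buildBands(sourceGeometry("point",
                                                unlist(cfg$source)),
                                 bandScheme(unlist(cfg$breaks))),
                      unlist(cfg$rr_by_band)),
    icar = rrIcarField(cfg$precision %||% 10),
    block = rrBlock(unlist(cfg$block_areas), cfg$rr %||% 3))
  sim <- simulateCounts(lat$geography, surface, adjacency = lat$adjacency,
                        n_age_bands = cfg$age_bands %||% 18,
                        mean_py = cfg$mean_py %||% 300, seed = cfg$seed)
  dir.create(o$outdir, recursive = TRUE, showWarnings = FALSE)
  writeTable(sim$counts, file.path(o$outdir, "counts.csv"))
  writeTable(sim$population, file.path(o$outdir, "population.csv"))
  write.csv(as.data.frame(sim$reference_rates),
            file.path(o$outdir, "reference_rates.csv"), row.names = FALSE)
  write.csv(data.frame(area_id = names(sim$truth), rr = sim$truth),
            file.path(o$outdir, "truth.csv"), row.names = FALSE)
  writeAreaGeoJSON(lat$geography, file.path(o$outdir, "areas.geojson"))
  writeAdjacency(lat$adjacency, file.path(o$outdir, "adjacency.txt"))
  cat("fixture set written to", o$outdir, "\n")

} else if (cmd == "bands") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--counts", type = "character"),
    make_option("--pop", type = "character"),
    make_option("--rates", type = "character"),
    make_option("--geography", type = "character"),
    make_option("--crs", type = "character", default = "planar-metric"),
    make_option("--age-bands", type = "integer", default = 18L,
                dest = "age_bands"),
    make_option("--source", type = "character"),
    make_option("--breaks", type = "character"),
    make_option("--centroid", type = "character",
                default = "geometric_centroid"),
    make_option("--outdir", type = "character", default = "."))),
    args = rest)
  inp <- read_inputs(o)
  src <- sourceGeometry("point", as.numeric(strsplit(o$source, ",")[[1]]))
  bands <- buildBands(src, bandScheme(as.numeric(
    strsplit(o$breaks, ",")[[1]])))
  mem <- selectAreas(inp$geo, bands, method = o$centroid)
  tbl <- bandRisks(mem, inp$counts, inp$pop, inp$rates)
  tests <- bandTests(tbl, scores = bandMidpoints(bands))
  dir.create(o$outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(tbl), file.path(o$outdir, "band_risks.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    homogeneity = list(statistic = tests$homogeneity$statistic,
                       df = tests$homogeneity$df,
                       p = tests$homogeneity$p_value),
    trend = list(statistic = tests$trend$statistic,
                 p = tests$trend$p_value)),
    file.path(o$outdir, "band_tests.json"), auto_unbox = TRUE, digits = NA)
  writeBandRegions(bands, file.path(o$outdir, "band_regions.geojson"))
  print(tbl); print(tests$homogeneity); print(tests$trend)

} else if (cmd == "map") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--counts", type = "character"),
    make_option("--pop", type = "character"),
    make_option("--rates", type = "character"),
    make_option("--geography", type = "character"),
    make_option("--crs", type = "character", default = "planar-metric"),
    make_option("--age-bands", type = "integer", default = 18L,
                dest = "age_bands"),
    make_option("--adjacency", type = "character", default = NULL),
    make_option("--rule", type = "character", default = "queen"),
    make_option("--seed", type = "integer"),
    make_option("--iter", type = "integer", default = 11000L),
    make_option("--burn", type = "integer", default = 1000L),
    make_option("--thin", type = "integer", default = 5L),
    make_option("--outdir", type = "character", default = "."))),
    args = rest)
  if (is.null(o$seed)) stop("--seed is mandatory for the map command")
  inp <- read_inputs(o)
  adj <- if (!is.null(o$adjacency)) readAdjacency(o$adjacency)
         else buildAdjacency(inp$geo, o$rule)
  ids <- adj$area_id
  E <- expectedCount(inp$pop, inp$rates)[ids]
  E[is.na(E)] <- 0
  O <- tapply(inp$counts$events, inp$counts$area_id, sum)[ids]
  O[is.na(O)] <- 0
  fld <- smoothedRiskField(as.numeric(O), as.numeric(E), adj,
                           seed = o$seed, n_iter = o$iter,
                           n_burn = o$burn, thin = o$thin)
  dir.create(o$outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(fld), file.path(o$outdir, "risk_field.csv"),
            row.names = FALSE)
  writeAreaGeoJSON(inp$geo, file.path(o$outdir, "risk_field.geojson"),
                   properties = as.data.frame(fld))
  print(utils::head(as.data.frame(fld)))
  cat("risk field written to", o$outdir, "\n")

} else usage()
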