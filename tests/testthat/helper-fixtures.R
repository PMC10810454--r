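# Shared fixtures: tiny maps and hand-built utilization distributions.

# unit-square exhibit split into two equal vertical halves
twoFeatureMap <- function() {
  ExhibitMap(
    boundary = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    featurePolygons = list(
      L = cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1)),
      R = cbind(c(0.5, 1, 1, 0.5), c(0, 0, 1, 1))),
    checkCell = 0.05)
}

# wrap a raw non-negative matrix into a valid UD (normalised, all in bounds)
makeUD <- function(dens, cellSize = 1, individual = "ind", period = "all",
                   origin = c(0, 0)) {
  dens <- dens / (sum(dens) * cellSize^2)
  new("UtilizationDistribution",
      individual = individual, period = period, origin = origin,
      cellSize = cellSize, density = dens,
      inBounds = matrix(TRUE, nrow(dens), ncol(dens)),
      bandwidth = 1, nLocations = 1L)
}

# full-grid range estimate (mask everywhere) or from an explicit mask
makeRange <- function(ud, mask = NULL, level = 0.95) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ud@density), ncol(ud@density))
  new("RangeEstimate", individual = ud@individual, period = ud@period,
      level = level, mask = mask, area = sum(mask) * ud@cellSize^2,
      origin = ud@origin, cellSize = ud@cellSize)
}

# small normalised record table for electivity / pipeline tests
syntheticRecords <- function(seed = 42, n = 6, days = 200) {
  cfg <- simulationConfig(nIndividuals = n, studyDays = days, seed = seed)
  simulateCohort(cfg)
}
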