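#' @include synthetic.R overlap.R inference.R
NULL

#' Pipeline configuration
#'
#' Validates and bundles the knobs of [runPipeline()].
#'
#' @param locations path to the locations CSV ([readLocations()] dialect),
#'   or a ready data.frame of records.
#' @param boundary GeoJSON boundary path, or NULL to use the packaged
#'   schematic exhibit.
#' @param features GeoJSON features path, feature-area table/CSV, or NULL.
#' @param outputDir directory for the output bundle.
#' @param cellSize analysis grid resolution (m); default 0.25.
#' @param homeLevel,coreLevel isopleth levels; core must be below home,
#'   both strictly in (0, 1).
#' @param udoiThreshold degree / binary-edge cut-off; default 0.01.
#' @param minLocations minimum records per individual-period; default 10.
#' @param renormalize renormalise truncated UDs before the UDOI integral;
#'   default FALSE.
#' @param schema column mapping for [readLocations()].
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return a `"pipelineConfig"` list.
#' @export
pipelineConfig <- function(locations, boundary = NULL, features = NULL,
                           outputDir = tempfile("exhibitspace_"),
                           cellSize = 0.25, homeLevel = 0.95,
                           coreLevel = 0.50, udoiThreshold = 0.01,
                           minLocations = 10, renormalize = FALSE,
                           schema = NULL, seed = 1) {
  if (!(homeLevel > 0 && homeLevel < 1 && coreLevel > 0 && coreLevel < 1))
    stop("isopleth levels must lie strictly between 0 and 1")
  if (coreLevel >= homeLevel)
    stop("core level must be below the home-range level")
  cfg <- list(locations = locations, boundary = boundary,
              features = features, outputDir = outputDir,
              cellSize = cellSize, homeLevel = homeLevel,
              coreLevel = coreLevel, udoiThreshold = udoiThreshold,
              minLocations = minLocations, renormalize = renormalize,
              schema = schema, seed = seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full space-use analysis
#'
#' Sequences the whole analysis: read/normalise locations, estimate
#' per-individual-period utilization distributions and home-range /
#' core-area isopleths, compute dyadic UDOI at the three space-use levels,
#' degree, the territoriality profile and seasonal edge lists, electivity
#' per period / season / time of day / overall, group summaries, and the
#' nonparametric group tests.  Every table is written as CSV into the
#' output directory together with a JSON run manifest.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list of all computed tables (and the manifest).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load_exhibit"
  out <- list()
  manifest <- list(config = unclass(config[setdiff(names(config), "locations")]),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   r_version = as.character(getRversion()))
  tryCatch({
    map <- if (is.null(config$boundary)) {
      if (is.null(config$features)) table1Exhibit()
      else exhibitFromFeatureTable(config$features)
    } else loadExhibit(config$boundary, config$features)

    stage <- "observations"
    rec <- if (is.data.frame(config$locations)) config$locations
           else if (is.null(config$schema)) readLocations(config$locations)
           else readLocations(config$locations, schema = config$schema)
    if (is.null(rec$period))
      rec <- normalizeLocations(rec, map)
    utils::write.csv(rec, file.path(config$outputDir, "locations_normalized.csv"),
                     row.names = FALSE)
    manifest$n_records <- nrow(rec)

    stage <- "homerange"
    fit <- estimateRanges(rec, map, cellSize = config$cellSize,
                          levels = c(home = config$homeLevel,
                                     core = config$coreLevel),
                          minLocations = config$minLocations)
    utils::write.csv(fit$areas, file.path(config$outputDir, "range_areas.csv"),
                     row.names = FALSE)
    out$areas <- fit$areas

    stage <- "overlap"
    ov <- udoiTable(fit, homeLevel = config$homeLevel,
                    coreLevel = config$coreLevel,
                    renormalize = config$renormalize)
    deg <- degreeTable(ov, threshold = config$udoiThreshold)
    prof <- territorialityProfile(ov, deg)
    edges <- edgeList(ov, threshold = config$udoiThreshold)
    utils::write.csv(ov, file.path(config$outputDir, "udoi_dyads.csv"),
                     row.names = FALSE)
    utils::write.csv(deg, file.path(config$outputDir, "degree.csv"),
                     row.names = FALSE)
    utils::write.csv(prof$summary,
                     file.path(config$outputDir, "territoriality_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(edges, file.path(config$outputDir, "edges_seasonal.csv"),
                     row.names = FALSE)
    out$overlaps <- ov; out$degrees <- deg
    out$profile <- prof; out$edges <- edges

    stage <- "electivity"
    elect <- list()
    for (strat in c("overall", "season", "period", "time_block")) {
      usage <- observedUse(rec, map, stratifyBy = strat)
      elect[[strat]] <- electivityTable(usage, map)
      utils::write.csv(elect[[strat]],
                       file.path(config$outputDir,
                                 paste0("electivity_", strat, ".csv")),
                       row.names = FALSE)
    }
    esum <- groupPreferenceSummary(elect$overall)
    utils::write.csv(esum, file.path(config$outputDir,
                                     "electivity_group_summary.csv"),
                     row.names = FALSE)
    out$electivity <- elect; out$electivitySummary <- esum

    stage <- "group_inference"
    usageOverall <- observedUse(rec, map, stratifyBy = "overall")
    tests <- list(
      feature_preference = featurePreferenceTests(usageOverall, map),
      seasonal = seasonalElectivityTests(elect$season),
      time_of_day = timeOfDayTests(elect$time_block))
    for (nm in names(tests))
      utils::write.csv(tests[[nm]],
                       file.path(config$outputDir, paste0("tests_", nm, ".csv")),
                       row.names = FALSE)
    out$tests <- tests

    manifest$status <- "OK"
  }, error = function(e) {
    manifest$status <<- "FAILED"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
  })
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (identical(manifest$status, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s",
                 manifest$failed_stage, manifest$error))
  out$manifest <- manifest
  invisible(out)
}
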