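#' @include opponent-channels.R datapath.R image-io.R
NULL

#' Default run configuration
#'
#' @return a named list with the pipeline defaults: 3x3 single-pixel-center
#'   receptive fields for all channels at zero eccentricity, fixation at the
#'   image center, 10 pixels per degree, a 5-degree full fovea, batch
#'   engine, no fixed-point quantization.
#' @export
defaultRunConfig <- function() {
  list(
    input = NULL,            # path, or list(kind=, size=, ... , seed=)
    outputDir = NULL,
    geometry = list(fixation = NULL,       # NULL = image center
                    pixelsPerDegree = 10,
                    foveaDeg = 5,          # full angle; half-angle = /2
                    viewingDistance = NULL,
                    rfIntercept = 3, rfSlope = 0.5),
    fields = list(K = list(size = 3), M = list(size = 3)),
    fixedPoint = "off",      # "off" or integer fraction bits
    engine = "batch",
    seed = 1L,
    logLevel = "info"
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [defaultRunConfig()] (file entries
#' win; nested blocks merge shallowly).
#'
#' @param path YAML file.
#' @return a run-configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (nm in names(user)) {
    if (nm %in% c("geometry", "fields") && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

#' Validate a run configuration
#'
#' Checks the whole configuration and reports every invalid field together
#' rather than stopping at the first.
#'
#' @param config a run-configuration list (see [defaultRunConfig()]).
#' @return the config, invisibly, if valid; otherwise stops with all
#'   problems listed.
#' @export
validateRunConfig <- function(config) {
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)
  if (is.null(config$input)) add("input: missing (path or fixture spec)")
  else if (is.character(config$input) && !file.exists(config$input))
    add(sprintf("input: file not found: %s", config$input))
  else if (is.list(config$input) && is.null(config$input$kind))
    add("input: fixture spec needs a 'kind'")
  if (is.null(config$outputDir)) add("outputDir: missing")
  g <- config$geometry
  if (!is.null(g$pixelsPerDegree) && g$pixelsPerDegree <= 0)
    add("geometry.pixelsPerDegree: must be > 0")
  if (!is.null(g$foveaDeg) && g$foveaDeg <= 0)
    add("geometry.foveaDeg: must be > 0")
  if (!is.null(g$viewingDistance) && g$viewingDistance < 0)
    add("geometry.viewingDistance: must be >= 0")
  for (ch in c("K", "M")) {
    fs <- config$fields[[ch]]$size
    if (!is.null(fs) && (fs < 1 || fs %% 2 == 0))
      add(sprintf("fields.%s.size: must be odd >= 1", ch))
  }
  fp <- config$fixedPoint
  if (!identical(fp, "off") &&
      (!is.numeric(fp) || fp != round(fp) || fp < 1 || fp > 24))
    add("fixedPoint: must be 'off' or an integer in [1, 24]")
  if (!config$engine %in% c("batch", "stream"))
    add("engine: must be 'batch' or 'stream'")
  if (length(probs))
    stop(paste0("invalid configuration:\n  ",
                paste(probs, collapse = "\n  ")), call. = FALSE)
  invisible(config)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full retinal-coding pipeline
#'
#' Image in, region-gated channel maps out: reads (or generates) the input
#' raster, maps it to L/M/S cone planes, computes the K, M and P opponent
#' maps under the configured geometry and engine, and writes the artifact
#' set -- one 16-bit offset PGM per channel, a CSV of per-channel summary
#' statistics, and a JSON report recording the configuration (and its
#' hash), streaming latencies and the datapath resource totals. The run is
#' deterministic given the configuration; the stream and batch engines
#' produce byte-identical artifacts.
#'
#' @param config a run-configuration list (see [defaultRunConfig()],
#'   [readRunConfig()]); validated with [validateRunConfig()] first.
#' @return invisibly, a list with the channel maps, the summary data.frame
#'   and the report list; artifacts are written under `config$outputDir`.
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  image <- if (is.character(config$input)) {
    readImage(config$input)
  } else {
    spec <- config$input
    args <- spec[setdiff(names(spec), "kind")]
    if (is.null(args$seed)) args$seed <- config$seed
    lapply_names <- c("value", "fg", "bg")
    for (nm in lapply_names)
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    do.call(generateFixture, c(list(kind = spec$kind), args))
  }
  cones <- rgbToConePlanes(image)
  h <- imageHeight(cones); w <- imageWidth(cones)
  g <- config$geometry
  fixation <- if (is.null(g$fixation)) c((w + 1) / 2, (h + 1) / 2)
              else unlist(g$fixation)
  geometry <- retinalGeometry(
    fixation = fixation,
    pixelsPerDegree = g$pixelsPerDegree,
    foveaHalfAngle = g$foveaDeg / 2,
    viewingDistance = g$viewingDistance,
    rfIntercept = if (is.null(g$rfIntercept)) 3 else g$rfIntercept,
    rfSlope = if (is.null(g$rfSlope)) 0.5 else g$rfSlope)
  fb <- if (identical(config$fixedPoint, "off")) NULL
        else as.integer(config$fixedPoint)
  fields <- list(
    K = rfFromConfig(utils::modifyList(list(size = 3L),
                                       config$fields$K %||% list())),
    M = rfFromConfig(utils::modifyList(list(size = 3L),
                                       config$fields$M %||% list())))
  maps <- channelMaps(cones, geometry, fields = fields,
                      engine = config$engine, fractionBits = fb)

  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  outPath <- function(f) file.path(config$outputDir, f)
  for (ch in names(maps))
    writePGM16(maps[[ch]]@map, outPath(sprintf("channel_%s.pgm", ch)))
  summ <- channelSummary(maps)
  utils::write.csv(summ, outPath("summary.csv"), row.names = FALSE)

  # latency of the streaming delivery per channel field size
  sizes <- sort(unique(c(fields$K@size, fields$M@size,
                         rfSizeAt(max(eccentricityGrid(geometry, c(h, w))),
                                  geometry))))
  latencies <- stats::setNames(
    lapply(sizes, function(s) (s - 1L) * w + s), paste0("size", sizes))
  costs <- defaultUnitCosts()
  res <- resourceReport(
    c(pipeline = costs$rf3x3$project, R_G_dup = costs$rg_shared_cost),
    "pipeline", "R_G_dup")
  # the computational configuration: everything but the output location,
  # so identical analyses hash (and re-run) identically wherever they write
  compCfg <- config[setdiff(names(config), "outputDir")]
  report <- list(
    configHash = configHash(compCfg),
    config = compCfg,
    image = list(width = w, height = h),
    latencyPixels = latencies,
    resources = list(withSharing = res@withSharing,
                     withoutSharing = res@withoutSharing,
                     savingsPercent = res@savingsPercent))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE),
             outPath("report.json"))
  invisible(list(maps = maps, summary = summ, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
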