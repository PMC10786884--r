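#' Default pipeline configuration
#'
#' All parameters of the end-to-end workflow with their defaults: a 300 x 300
#' pixel study area (10 m pixels, 0.01 ha) with class shares mirroring a
#' degraded raised-bog landscape (cutaway 10%, cutover 11%, grassland 43%,
#' forestry 21%, remnant peatland 13%, water 1%, built-up 1%); ten scenes
#' with contiguous cloud fields of 5--30% cover and per-band reflectance
#' noise SD 0.01; a scene filter threshold of 0.35 (above the generator's
#' cloud range, so all synthetic scenes contribute -- on real archives with
#' thousands of acquisitions a threshold of 0.10 is the conventional
#' choice); 10 training polygons of 4 x 4 pixels per class; a 20-tree forest
#' with sqrt-features splits; 1460 validation points with a 50-point
#' stratum floor; and error-free reference labelling. Every stage seed is
#' derived from the single master \code{seed}.
#'
#' @param seed master integer seed.
#' @return named list of parameters.
#' @export
defaultConfig <- function(seed = 421L) {
  list(
    width = 300L, height = 300L,
    proportions = c(0.10, 0.11, 0.43, 0.21, 0.13, 0.01, 0.01),
    patchScale = 20, pixelSizeHa = 0.01,
    nScenes = 10L, cloudFractionRange = c(0.05, 0.30), noiseSd = 0.01,
    maxCloudFraction = 0.35,
    nPolygonsPerClass = rep(10L, 7L), polygonSize = 4L,
    nTrees = 20L, variablesPerSplit = "sqrt",
    totalValidationPoints = 1460L, minPerStratum = 50L,
    referenceErrorRate = 0,
    efTablePath = NULL,
    seed = as.integer(seed)
  )
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges, the seed, and path resolvability before any
#' stage runs; returns the config (with defaults filled in) or stops with
#' the offending field named.
#'
#' @param config a (possibly partial) configuration list; missing entries
#'   take the \code{\link{defaultConfig}} values.
#' @return the completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  cfg <- defaultConfig()
  cfg[names(config)] <- config
  fail <- function(f, why) stop("config field '", f, "': ", why)
  if (cfg$width < 1 || cfg$height < 1) fail("width/height", "must be >= 1")
  if (length(cfg$proportions) != 7 || any(cfg$proportions < 0) ||
      abs(sum(cfg$proportions) - 1) > 1e-9)
    fail("proportions", "must be 7 non-negative values summing to 1")
  if (cfg$patchScale < 1) fail("patchScale", "must be >= 1")
  if (cfg$pixelSizeHa <= 0) fail("pixelSizeHa", "must be > 0")
  if (cfg$nScenes < 1) fail("nScenes", "must be >= 1")
  r <- cfg$cloudFractionRange
  if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1)
    fail("cloudFractionRange", "must be c(lo, hi) within [0, 1]")
  if (cfg$noiseSd < 0) fail("noiseSd", "must be >= 0")
  if (cfg$maxCloudFraction < 0 || cfg$maxCloudFraction > 1)
    fail("maxCloudFraction", "must be in [0, 1]")
  if (cfg$nTrees < 1) fail("nTrees", "must be >= 1")
  if (cfg$totalValidationPoints < 1) fail("totalValidationPoints", "must be >= 1")
  if (cfg$minPerStratum < 0) fail("minPerStratum", "must be >= 0")
  if (cfg$referenceErrorRate < 0 || cfg$referenceErrorRate > 1)
    fail("referenceErrorRate", "must be in [0, 1]")
  if (!is.null(cfg$efTablePath) && !file.exists(cfg$efTablePath))
    fail("efTablePath", paste0("file not found: ", cfg$efTablePath))
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed", "must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stageSeeds <- function(seed) {
  s <- as.integer(seed)
  list(map = s + 11L, scenes = s + 23L, polygons = s + 37L,
       forest = s + 41L, points = s + 53L, reference = s + 67L)
}

artifactPath <- function(outdir, name) file.path(outdir, name)

requireArtifact <- function(path, stage) {
  if (!file.exists(path))
    stop(stage, ": missing upstream artifact, expected file ", path)
  path
}

#' Pipeline stages
#'
#' File-based stages of the workflow, each reading its inputs from and
#' writing its outputs to \code{outdir}: \code{stageSimulate} (truth map,
#' scene series, scene index, training polygons), \code{stageComposite}
#' (12-layer feature stack), \code{stageClassify} (class map, variable
#' importance, serialised model), \code{stageAssess} (confusion matrix,
#' accuracy report, unbiased area estimates) and \code{stageEmissions}
#' (tiered emission report on the estimated areas). A missing upstream
#' artifact is an error naming the expected file.
#'
#' @param config a configuration list (see \code{\link{validateConfig}}).
#' @param outdir output directory, created if needed.
#' @return each stage returns its principal objects, invisibly.
#' @name pipelineStages
NULL

#' @rdname pipelineStages
#' @export
stageSimulate <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stageSeeds(cfg$seed)
  truth <- generateClassMap(cfg$width, cfg$height, cfg$proportions,
                            cfg$patchScale, seed = seeds$map,
                            pixelSizeHa = cfg$pixelSizeHa)
  sig <- defaultSignatures(noiseSd = cfg$noiseSd)
  series <- generateSceneSeries(truth, sig, cfg$nScenes,
                                cfg$cloudFractionRange, seed = seeds$scenes)
  polys <- generateTrainingPolygons(truth, cfg$nPolygonsPerClass,
                                    cfg$polygonSize, seed = seeds$polygons)
  writeClassMapTiff(truth, artifactPath(outdir, "truth.tif"))
  files <- sprintf("scene_%02d.tif", seq_along(series))
  for (i in seq_along(series))
    writeSceneTiff(series[[i]], artifactPath(outdir, files[i]))
  writeSceneIndex(files, series, artifactPath(outdir, "scene_index.csv"))
  writePolygonsGeoJSON(polys, artifactPath(outdir, "training_polygons.geojson"))
  invisible(list(truth = truth, series = series, polygons = polys))
}

#' @rdname pipelineStages
#' @export
stageComposite <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  idx <- utils::read.csv(
    requireArtifact(artifactPath(outdir, "scene_index.csv"), "composite"),
    stringsAsFactors = FALSE)
  series <- lapply(idx$filename, function(f)
    readSceneTiff(requireArtifact(artifactPath(outdir, f), "composite")))
  stack <- buildFeatureStack(series, cfg$maxCloudFraction)
  writeCompositeTiff(stack, artifactPath(outdir, "composite.tif"))
  invisible(stack)
}

#' @rdname pipelineStages
#' @export
stageClassify <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  seeds <- stageSeeds(cfg$seed)
  stack <- readCompositeTiff(
    requireArtifact(artifactPath(outdir, "composite.tif"), "classify"))
  polys <- readPolygonsGeoJSON(
    requireArtifact(artifactPath(outdir, "training_polygons.geojson"),
                    "classify"))
  train <- extractTrainingPixels(stack, polys)
  model <- trainForest(train, cfg$nTrees, cfg$variablesPerSplit,
                       seed = seeds$forest)
  map <- predictMap(model, stack, pixelSizeHa = cfg$pixelSizeHa)
  writeClassMapTiff(map, artifactPath(outdir, "classmap.tif"))
  utils::write.csv(variableImportance(model),
                   artifactPath(outdir, "variable_importance.csv"),
                   row.names = FALSE)
  writeForestJSON(model, artifactPath(outdir, "forest_model.json"))
  invisible(list(model = model, map = map, training = train))
}

#' @rdname pipelineStages
#' @export
stageAssess <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  seeds <- stageSeeds(cfg$seed)
  map <- readClassMapTiff(
    requireArtifact(artifactPath(outdir, "classmap.tif"), "assess"))
  truth <- readClassMapTiff(
    requireArtifact(artifactPath(outdir, "truth.tif"), "assess"))
  areas <- classAreasHa(map)
  alloc <- allocateStratifiedSample(areas, cfg$totalValidationPoints,
                                    cfg$minPerStratum)
  pts <- drawValidationPoints(map, alloc, seed = seeds$points)
  pts <- simulateReferenceLabels(pts, truth, cfg$referenceErrorRate,
                                 seed = seeds$reference)
  cm <- buildConfusionMatrix(pts$mapClass, pts$refClass, areas)
  acc <- accuracyReport(cm)
  est <- unbiasedAreaEstimates(cm)
  g <- classGrid(map); tg <- classGrid(truth)
  agreement <- 100 * mean(g == tg)
  writeConfusionCSV(cm, artifactPath(outdir, "confusion_matrix.csv"))
  writeConfusionJSON(cm, artifactPath(outdir, "confusion_matrix.json"))
  utils::write.csv(
    data.frame(class = names(acc$ua), UA_pct = acc$ua, PA_pct = acc$pa,
               row.names = NULL),
    artifactPath(outdir, "accuracy_by_class.csv"), row.names = FALSE)
  utils::write.csv(est, artifactPath(outdir, "area_estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(oa_count_pct = acc$oa, oa_area_weighted_pct = areaWeightedOA(cm),
         n_points = acc$n, true_pixel_agreement_pct = agreement),
    artifactPath(outdir, "assessment_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(cm = cm, accuracy = acc, estimates = est,
                 agreementPct = agreement, allocation = alloc))
}

#' @rdname pipelineStages
#' @export
stageEmissions <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  est <- utils::read.csv(
    requireArtifact(artifactPath(outdir, "area_estimates.csv"), "emissions"),
    stringsAsFactors = FALSE)
  areas <- stats::setNames(est$areaHa, lucipName(as.integer(est$class)))
  efs <- loadEmissionFactors(cfg$efTablePath)
  report <- computeEmissions(areas, efs)
  f <- formatEmissionTable(report)
  utils::write.csv(report$perClass, artifactPath(outdir, "emissions.csv"),
                   row.names = FALSE)
  utils::write.csv(f$totals, artifactPath(outdir, "emission_totals.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' Run the full workflow
#'
#' Chains the five stages (simulate, composite, classify, assess, emissions)
#' on a single configuration, writes all artifacts plus a JSON run manifest
#' (configuration, derived stage seeds, package version, per-file MD5
#' checksums) to \code{outdir}, and returns the in-memory results. Two runs
#' with the same configuration produce identical artifacts.
#'
#' @param config a configuration list (see \code{\link{validateConfig}}).
#' @param outdir output directory.
#' @return list with elements \code{truth}, \code{series}, \code{polygons},
#'   \code{stack}, \code{model}, \code{map}, \code{assessment},
#'   \code{emissions}, invisibly.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("peatluc_run_")) {
  cfg <- validateConfig(config)
  sim <- stageSimulate(cfg, outdir)
  stack <- stageComposite(cfg, outdir)
  cls <- stageClassify(cfg, outdir)
  assess <- stageAssess(cfg, outdir)
  emis <- stageEmissions(cfg, outdir)
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package = "peatluc",
    version = as.character(utils::packageVersion("peatluc")),
    config = cfg[setdiff(names(cfg), "efTablePath")],
    efTablePath = if (is.null(cfg$efTablePath)) "packaged" else cfg$efTablePath,
    stageSeeds = stageSeeds(cfg$seed),
    checksums = as.list(stats::setNames(tools::md5sum(files),
                                        basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = sim$truth, series = sim$series,
                 polygons = sim$polygons, stack = stack,
                 model = cls$model, map = cls$map,
                 assessment = assess, emissions = emis,
                 outdir = outdir))
}
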