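#' Accessors for the package's S4 containers
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("classGrid", function(x) standardGeneric("classGrid"))
#' @rdname accessors
#' @export
setMethod("classGrid", "ClassMap", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("pixelSizeHa", function(x) standardGeneric("pixelSizeHa"))
#' @rdname accessors
#' @export
setMethod("pixelSizeHa", "ClassMap", function(x) x@pixelSizeHa)

#' @rdname accessors
#' @export
setGeneric("sceneBands", function(x) standardGeneric("sceneBands"))
#' @rdname accessors
#' @export
setMethod("sceneBands", "Scene", function(x) x@bands)
#' @rdname accessors
#' @export
setMethod("sceneBands", "BandSet", function(x) x@bands)

#' @rdname accessors
#' @export
setGeneric("sceneQA", function(x) standardGeneric("sceneQA"))
#' @rdname accessors
#' @export
setMethod("sceneQA", "Scene", function(x) x@qa)

#' @rdname accessors
#' @export
setGeneric("cloudFraction", function(x) standardGeneric("cloudFraction"))
#' @rdname accessors
#' @export
setMethod("cloudFraction", "Scene", function(x) x@cloudFraction)

#' @rdname accessors
#' @export
setGeneric("signatureMeans", function(x) standardGeneric("signatureMeans"))
#' @rdname accessors
#' @export
setMethod("signatureMeans", "SpectralSignatureSet", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("noiseSd", function(x) standardGeneric("noiseSd"))
#' @rdname accessors
#' @export
setMethod("noiseSd", "SpectralSignatureSet", function(x) x@noiseSd)

#' @rdname accessors
#' @export
setGeneric("stackFeatures", function(x) standardGeneric("stackFeatures"))
#' @rdname accessors
#' @export
setMethod("stackFeatures", "CompositeImage", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "CompositeImage", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("polygonRings", function(x) standardGeneric("polygonRings"))
#' @rdname accessors
#' @export
setMethod("polygonRings", "TrainingPolygons", function(x) x@polygons)

#' @rdname accessors
#' @export
setGeneric("polygonClass", function(x) standardGeneric("polygonClass"))
#' @rdname accessors
#' @export
setMethod("polygonClass", "TrainingPolygons", function(x) x@classCode)

#' @rdname accessors
#' @export
setGeneric("trainingFeatures", function(x) standardGeneric("trainingFeatures"))
#' @rdname accessors
#' @export
setMethod("trainingFeatures", "TrainingSet", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("trainingLabels", function(x) standardGeneric("trainingLabels"))
#' @rdname accessors
#' @export
setMethod("trainingLabels", "TrainingSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setMethod("classCounts", "TrainingSet", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("mappedAreasHa", function(x) standardGeneric("mappedAreasHa"))
#' @rdname accessors
#' @export
setMethod("mappedAreasHa", "ConfusionMatrix", function(x) x@mappedAreasHa)

#' Class areas of a ClassMap by pixel counting
#'
#' @param x a \linkS4class{ClassMap}.
#' @param codes integer class codes to tabulate (default 1--7).
#' @return named numeric vector of areas in hectares (names = class codes).
#' @export
classAreasHa <- function(x, codes = 1:7) {
  stopifnot(is(x, "ClassMap"))
  cnt <- tabulate(factor(x@grid[x@grid != 0L], levels = codes),
                  nbins = length(codes))
  stats::setNames(cnt * x@pixelSizeHa, as.character(codes))
}

setMethod("show", "ClassMap", function(object) {
  d <- dim(object@grid)
  cat("ClassMap:", d[1], "x", d[2], "pixels,",
      format(object@pixelSizeHa), "ha/pixel\n")
  a <- classAreasHa(object)
  pres <- a[a > 0]
  cat("  classes present:",
      paste0(lucipName(as.integer(names(pres))), " (",
             format(pres, trim = TRUE), " ha)", collapse = ", "), "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@bands)
  cat("Scene", format(object@date), ":", d[1], "x", d[2],
      "pixels, 10 bands, cloud fraction",
      sprintf("%.3f", object@cloudFraction), "\n")
})

setMethod("show", "SpectralSignatureSet", function(object) {
  cat("SpectralSignatureSet: 7 classes x 10 bands, noise SD",
      paste(unique(object@noiseSd), collapse = "/"), "\n")
  print(round(object@means, 3))
})

setMethod("show", "CompositeImage", function(object) {
  d <- dim(object@features)
  nNoData <- sum(object@provenance == 0L)
  cat("CompositeImage:", d[1], "x", d[2], "pixels, 12 layers (",
      paste(stackFeatureNames(), collapse = ","), ")\n", sep = "")
  cat("  clear-observation counts:", min(object@provenance), "-",
      max(object@provenance), "; nodata pixels:", nNoData, "\n")
})

setMethod("show", "TrainingPolygons", function(object) {
  cat("TrainingPolygons:", length(object@polygons), "polygons\n")
  print(table(lucipName(object@classCode)))
})

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", nrow(object@features), "pixels x",
      ncol(object@features), "features\n")
  print(object@counts)
})

setMethod("show", "ForestModel", function(object) {
  cat("ForestModel:", object@nTrees, "trees,",
      object@variablesPerSplit, "variables per split, seed",
      object@seed, "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = map, cols = reference), n =",
      sum(object@counts), "\n")
  print(object@counts)
})
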