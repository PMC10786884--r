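# Raster file I/O.
#
# No georeferenced-TIFF writer is available to the package, so rasters are
# stored as multi-page 32-bit-float TIFF files with a JSON sidecar
# ("<path>.json") that carries the layer names, a per-layer offset/scale
# (layers are rescaled into [0, 1] for storage), an integer flag per layer
# (integer layers are rounded on read, making their round-trip exact), the
# pixel size and free-form metadata. Each data page is followed by the full
# set of nodata-mask pages (1 = nodata). Reflectance/index layers round-trip
# to float32 precision (|error| < 1e-6).

writeLayersTiff <- function(arr, path, integerLayers = NULL,
                            pixelSizeHa = NA_real_, meta = list()) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  k <- dim(arr)[3]
  layers <- dimnames(arr)[[3]]
  if (is.null(layers)) layers <- paste0("layer", seq_len(k))
  if (is.null(integerLayers)) integerLayers <- rep(FALSE, k)
  offset <- numeric(k); scale <- numeric(k)
  pages <- vector("list", 2L * k)
  for (i in seq_len(k)) {
    v <- arr[, , i]
    rng <- range(v, na.rm = TRUE, finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    offset[i] <- min(0, rng[1])
    scale[i] <- max(1, rng[2] - offset[i])
    s <- (v - offset[i]) / scale[i]
    s[is.na(s)] <- 0
    pages[[i]] <- s
    m <- matrix(0, nrow(v), ncol(v))
    m[is.na(v)] <- 1
    pages[[k + i]] <- m
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(layers = as.list(layers), offset = offset, scale = scale,
                  integer = integerLayers, pixelSizeHa = pixelSizeHa,
                  meta = meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

readLayersTiff <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  k <- length(side$layers)
  if (length(pages) != 2L * k)
    stop("malformed raster file ", path, ": expected ", 2L * k,
         " pages, found ", length(pages))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(NA_real_, c(h, w, k),
               dimnames = list(NULL, NULL, unlist(side$layers)))
  for (i in seq_len(k)) {
    v <- pages[[i]] * side$scale[i] + side$offset[i]
    if (isTRUE(side$integer[i])) v <- round(v)
    v[pages[[k + i]] > 0.5] <- NA_real_
    arr[, , i] <- v
  }
  list(array = arr, pixelSizeHa = side$pixelSizeHa, meta = side$meta)
}

#' Raster file I/O for the package's grid objects
#'
#' Scenes, class maps and composite images are written as multi-page
#' 32-bit-float TIFF files with a JSON sidecar holding layer names, scaling,
#' nodata masks, pixel size and metadata (see the package vignette for the
#' format). Integer layers (class codes, QA bits, provenance counts)
#' round-trip exactly; float layers to float32 precision.
#'
#' @param scene,map,stack the object to write.
#' @param path file path (conventionally \code{.tif}; a \code{.tif.json}
#'   sidecar is written alongside).
#' @return the writers return \code{path} invisibly; the readers return the
#'   reconstructed object.
#' @name rasterIO
NULL

#' @rdname rasterIO
#' @export
writeSceneTiff <- function(scene, path) {
  stopifnot(is(scene, "Scene"))
  arr <- array(NA_real_, dim(scene@bands) + c(0, 0, 1),
               dimnames = list(NULL, NULL, c(bandNames(), "QA")))
  arr[, , 1:10] <- scene@bands
  arr[, , 11] <- scene@qa
  writeLayersTiff(arr, path, integerLayers = c(rep(FALSE, 10), TRUE),
                  meta = list(date = format(scene@date),
                              cloudFraction = scene@cloudFraction))
}

#' @rdname rasterIO
#' @export
readSceneTiff <- function(path) {
  x <- readLayersTiff(path)
  qa <- x$array[, , "QA"]
  qa[is.na(qa)] <- 0
  b <- x$array[, , 1:10, drop = FALSE]
  dimnames(b) <- NULL
  new("Scene", bands = b,
      qa = matrix(as.integer(qa), nrow(qa), ncol(qa)),
      date = as.Date(x$meta$date),
      cloudFraction = as.numeric(x$meta$cloudFraction))
}

#' @rdname rasterIO
#' @export
writeClassMapTiff <- function(map, path) {
  stopifnot(is(map, "ClassMap"))
  arr <- array(as.numeric(map@grid), c(dim(map@grid), 1L),
               dimnames = list(NULL, NULL, "class"))
  writeLayersTiff(arr, path, integerLayers = TRUE,
                  pixelSizeHa = map@pixelSizeHa)
}

#' @rdname rasterIO
#' @export
readClassMapTiff <- function(path) {
  x <- readLayersTiff(path)
  g <- x$array[, , 1]
  new("ClassMap", grid = matrix(as.integer(g), nrow(g), ncol(g)),
      pixelSizeHa = as.numeric(x$pixelSizeHa))
}

#' @rdname rasterIO
#' @export
writeCompositeTiff <- function(stack, path) {
  stopifnot(is(stack, "CompositeImage"))
  arr <- array(NA_real_, dim(stack@features) + c(0, 0, 1),
               dimnames = list(NULL, NULL,
                               c(stackFeatureNames(), "provenance")))
  arr[, , 1:12] <- stack@features
  arr[, , 13] <- stack@provenance
  writeLayersTiff(arr, path, integerLayers = c(rep(FALSE, 12), TRUE))
}

#' @rdname rasterIO
#' @export
readCompositeTiff <- function(path) {
  x <- readLayersTiff(path)
  prov <- x$array[, , "provenance"]
  prov[is.na(prov)] <- 0
  new("CompositeImage", features = x$array[, , 1:12, drop = FALSE],
      provenance = matrix(as.integer(prov), nrow(prov), ncol(prov)))
}

#' GeoJSON I/O for labelled polygons
#'
#' Writes a \linkS4class{TrainingPolygons} as a GeoJSON FeatureCollection of
#' Polygon features with a \code{class_code} property, coordinates in pixel
#' units; reading reverses the mapping exactly (class codes and vertex order
#' preserved).
#'
#' @param polygons a \linkS4class{TrainingPolygons}.
#' @param path file path.
#' @return \code{writePolygonsGeoJSON}: \code{path} invisibly;
#'   \code{readPolygonsGeoJSON}: a \linkS4class{TrainingPolygons}.
#' @export
writePolygonsGeoJSON <- function(polygons, path) {
  stopifnot(is(polygons, "TrainingPolygons"))
  features <- lapply(seq_along(polygons@polygons), function(i) {
    ring <- polygons@polygons[[i]]
    coords <- lapply(seq_len(nrow(ring)), function(j)
      c(ring[j, 1], ring[j, 2]))
    list(type = "Feature",
         properties = list(class_code = polygons@classCode[i]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePolygonsGeoJSON
#' @export
readPolygonsGeoJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("malformed GeoJSON in ", path, ": not a FeatureCollection")
  polys <- list(); codes <- integer(0)
  for (f in obj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("malformed GeoJSON in ", path, ": geometry type must be Polygon")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    colnames(ring) <- c("x", "y")
    polys[[length(polys) + 1L]] <- ring
    code <- f$properties$class_code
    if (is.null(code)) stop("malformed GeoJSON in ", path,
                            ": feature lacks class_code property")
    codes <- c(codes, as.integer(code))
  }
  new("TrainingPolygons", polygons = polys, classCode = codes)
}

#' CSV and JSON I/O for confusion matrices
#'
#' The CSV carries one row per map class with the per-reference-class counts
#' and a \code{mapped_area_ha} column; the JSON form carries explicit
#' row/column class names. Both round-trip exactly.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @param path file path.
#' @export
writeConfusionCSV <- function(cm, path) {
  stopifnot(is(cm, "ConfusionMatrix"))
  df <- data.frame(class = rownames(cm@counts), cm@counts,
                   mapped_area_ha = cm@mappedAreasHa,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConfusionCSV
#' @export
readConfusionCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("class", "mapped_area_ha")),
                         drop = FALSE])
  rownames(counts) <- df$class
  confusionMatrixFromCounts(counts, df$mapped_area_ha)
}

#' @rdname writeConfusionCSV
#' @export
writeConfusionJSON <- function(cm, path) {
  stopifnot(is(cm, "ConfusionMatrix"))
  jsonlite::write_json(
    list(mapClasses = rownames(cm@counts),
         referenceClasses = colnames(cm@counts),
         counts = cm@counts,
         mappedAreasHa = as.numeric(cm@mappedAreasHa)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Packaged validation cross-tabulation
#'
#' A published seven-class validation cross-tabulation for a national
#' raised-bog land-use assessment (1460 stratified validation points),
#' shipped as the worked example for the accuracy statistics: rows = map
#' class, columns = reference class.
#'
#' @return integer matrix with class-name dimnames.
#' @export
packagedValidationCounts <- function() {
  path <- system.file("extdata", "validation_counts.csv",
                      package = "peatluc", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$class
  storage.mode(m) <- "integer"
  m
}

#' Scene-index CSV
#'
#' @param filenames character vector of per-scene raster files.
#' @param series the corresponding list of \linkS4class{Scene}.
#' @param path output CSV path.
#' @export
writeSceneIndex <- function(filenames, series, path) {
  utils::write.csv(
    data.frame(filename = filenames,
               date = vapply(series, function(s) format(s@date), ""),
               cloud_fraction = vapply(series, cloudFraction, numeric(1))),
    path, row.names = FALSE)
  invisible(path)
}
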