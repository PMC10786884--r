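#' Filter a scene series by cloud fraction
#'
#' Keeps exactly the scenes whose scene-level cloud fraction is strictly
#' below \code{maxFraction}, preserving order. An empty result is returned
#' with a warning (the compositor then refuses to run).
#'
#' @param series list of \linkS4class{Scene}.
#' @param maxFraction scalar in [0, 1]; comparison is strict \code{<}.
#' @return the filtered list.
#' @export
filterByCloudFraction <- function(series, maxFraction) {
  if (maxFraction < 0 || maxFraction > 1)
    stop("maxFraction must be in [0, 1]")
  keep <- vapply(series, cloudFraction, numeric(1)) < maxFraction
  out <- series[keep]
  if (length(out) == 0L)
    warning("no scene passes the cloud-fraction filter (< ",
            maxFraction, ")")
  out
}

#' Mask cloudy pixels of a scene to nodata
#'
#' Every pixel whose QA value has the opaque-cloud or cirrus bit set becomes
#' NA in all ten bands; clear pixels are unchanged.
#'
#' @param scene a \linkS4class{Scene}.
#' @return the masked \linkS4class{Scene} (QA band retained).
#' @export
maskClouds <- function(scene) {
  stopifnot(is(scene, "Scene"))
  cloudy <- qaIsCloudy(scene@qa)
  if (any(cloudy)) {
    b <- scene@bands
    idx <- which(cloudy)
    n <- length(scene@qa)
    for (k in 1:10) b[idx + (k - 1L) * n] <- NA_real_
    scene@bands <- b
  }
  scene
}

#' Per-pixel temporal median composite
#'
#' For each pixel and band, the median of the non-nodata observations across
#' the (already cloud-masked) series; a pixel with no clear observation in
#' any scene is nodata. With an even number of observations the median is the
#' mean of the two central values, per band independently.
#'
#' @param series non-empty list of \linkS4class{Scene} with congruent grids.
#' @return a \linkS4class{BandSet}.
#' @export
medianComposite <- function(series) {
  if (length(series) == 0L) stop("median composite: empty scene series")
  dims <- dim(series[[1]]@bands)
  for (s in series)
    if (!identical(dim(s@bands), dims))
      stop("median composite: scenes have incongruent grids")
  h <- dims[1]; w <- dims[2]
  nS <- length(series)
  out <- array(NA_real_, c(h, w, 10L), dimnames = list(NULL, NULL, bandNames()))
  for (b in 1:10) {
    m <- vapply(series, function(s) as.vector(s@bands[, , b]),
                numeric(h * w))
    if (nS == 1L) m <- matrix(m, ncol = 1L)
    out[, , b] <- matrix(rowMediansNA(m), h, w)
  }
  new("BandSet", bands = out)
}

#' Normalised Difference Vegetation Index
#'
#' NDVI = (NIR - Red) / (NIR + Red), computed per pixel from the B8 and B4
#' layers. Pixels where the denominator is zero, or where either input is
#' nodata, are nodata (no exception is raised).
#'
#' @param bands a \linkS4class{BandSet}.
#' @return numeric matrix in [-1, 1] with NA for nodata.
#' @export
ndvi <- function(bands) {
  stopifnot(is(bands, "BandSet"))
  normalisedDifference(bandLayer(bands, "B8"), bandLayer(bands, "B4"))
}

#' Normalised Difference Water Index
#'
#' NDWI = (NNIR - SWIR1) / (NNIR + SWIR1), from the B8a and B11 layers;
#' values of 0.5 and above indicate open water. Degenerate denominators give
#' nodata.
#'
#' @param bands a \linkS4class{BandSet}.
#' @return numeric matrix in [-1, 1] with NA for nodata.
#' @export
ndwi <- function(bands) {
  stopifnot(is(bands, "BandSet"))
  normalisedDifference(bandLayer(bands, "B8a"), bandLayer(bands, "B11"))
}

# one band as a matrix, robust to single-row/column grids
bandLayer <- function(bands, name) {
  b <- bands@bands[, , name, drop = FALSE]
  dim(b) <- dim(bands@bands)[1:2]
  b
}

normalisedDifference <- function(a, b) {
  s <- a + b
  out <- (a - b) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Nearest-neighbour upsampling of a 20 m grid to the 10 m grid
#'
#' Duplicates each source pixel into a \code{factor} x \code{factor} block,
#' preserving reflectance values exactly; the convention used for bringing
#' the native 20 m bands onto the common 10 m grid.
#'
#' @param grid numeric matrix (one band).
#' @param factor integer upsampling factor (default 2).
#' @return matrix with \code{factor}-fold duplicated rows and columns.
#' @export
upsampleNearest <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  grid[rep(seq_len(nrow(grid)), each = factor),
       rep(seq_len(ncol(grid)), each = factor), drop = FALSE]
}

#' Build the 12-layer feature stack from a scene series
#'
#' The full pre-processing chain: cloud-fraction filter (strict \code{<}),
#' QA cloud masking, per-pixel temporal median composite, then NDVI and NDWI
#' computed from the composited bands. Layers are stacked in the fixed order
#' B2, B3, B4, B5, B6, B7, B8, B8a, B11, B12, NDVI, NDWI, with a provenance
#' count of clear observations per pixel.
#'
#' @param series list of \linkS4class{Scene}.
#' @param maxCloudFraction scene-level filter threshold (strict \code{<}).
#' @return a \linkS4class{CompositeImage}.
#' @export
buildFeatureStack <- function(series, maxCloudFraction = 0.10) {
  kept <- filterByCloudFraction(series, maxCloudFraction)
  if (length(kept) == 0L)
    stop("feature stack failed at cloud-fraction filter: no surviving scene")
  masked <- lapply(kept, maskClouds)
  comp <- medianComposite(masked)
  prov <- Reduce(`+`, lapply(masked, function(s)
    matrix(as.integer(!is.na(s@bands[, , 1L])), nrow(s@qa), ncol(s@qa))))
  if (all(prov == 0L))
    stop("feature stack failed at median composite: no clear observation anywhere")
  h <- dim(comp@bands)[1]; w <- dim(comp@bands)[2]
  feat <- array(NA_real_, c(h, w, 12L),
                dimnames = list(NULL, NULL, stackFeatureNames()))
  feat[, , 1:10] <- comp@bands
  feat[, , "NDVI"] <- ndvi(comp)
  feat[, , "NDWI"] <- ndwi(comp)
  new("CompositeImage", features = feat, provenance = prov)
}
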