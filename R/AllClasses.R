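#' @import methods
NULL

#' SpectralSignatureSet: per-class mean reflectance signatures
#'
#' Holds a 7 x 10 matrix of per-class mean reflectances (rows = LUCIP classes
#' in code order, columns = the ten bands of \code{\link{bandNames}}) and a
#' per-band additive noise standard deviation, both unitless reflectance.
#'
#' @slot means numeric matrix, 7 x 10, values in [0, 1].
#' @slot noiseSd numeric vector of length 10, non-negative.
#' @seealso [defaultSignatures()]
#' @exportClass SpectralSignatureSet
setClass("SpectralSignatureSet",
  representation(means = "matrix", noiseSd = "numeric"),
  validity = function(object) {
    m <- object@means
    if (!is.numeric(m) || nrow(m) != 7L || ncol(m) != 10L)
      return("means must be a 7 x 10 numeric matrix")
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
      return("all signature means must be finite and in [0, 1]")
    if (length(object@noiseSd) != 10L || any(object@noiseSd < 0))
      return("noiseSd must be 10 non-negative values")
    TRUE
  }
)

#' ClassMap: a categorical land-use raster
#'
#' A single-band categorical raster over the seven LUCIP classes. The grid is
#' an integer matrix (row 1 = top of the map, row-major, pixel centres at
#' half-integer coordinates); value 0 marks nodata/outside-mask pixels.
#'
#' @slot grid integer matrix of class codes (0--7).
#' @slot pixelSizeHa numeric scalar, area of one pixel in hectares (> 0);
#'   0.01 ha corresponds to a 10 m pixel.
#' @exportClass ClassMap
setClass("ClassMap",
  representation(grid = "matrix", pixelSizeHa = "numeric"),
  validity = function(object) {
    g <- object@grid
    if (!all(g %in% 0:7)) return("grid values must be class codes 0-7")
    if (length(object@pixelSizeHa) != 1L || !is.finite(object@pixelSizeHa) ||
        object@pixelSizeHa <= 0)
      return("pixelSizeHa must be a single positive number")
    TRUE
  }
)

#' Scene: one acquisition date's reflectance raster with QA bitmask
#'
#' @slot bands numeric array height x width x 10, reflectance in [0, 1] or NA.
#' @slot qa integer matrix of QA bitmask values (see \code{\link{qaBits}}).
#' @slot date Date of acquisition.
#' @slot cloudFraction numeric in [0, 1]; equals the fraction of pixels with
#'   either cloud bit set.
#' @exportClass Scene
setClass("Scene",
  representation(bands = "array", qa = "matrix", date = "Date",
                 cloudFraction = "numeric"),
  validity = function(object) {
    b <- object@bands
    if (length(dim(b)) != 3L || dim(b)[3] != 10L)
      return("bands must be a height x width x 10 array")
    if (!identical(dim(object@qa), dim(b)[1:2]))
      return("qa grid must be congruent with the bands")
    v <- b[!is.na(b)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return("reflectance must be in [0, 1] or NA")
    cf <- object@cloudFraction
    if (length(cf) != 1L || cf < 0 || cf > 1)
      return("cloudFraction must be a single value in [0, 1]")
    qaFrac <- mean(qaIsCloudy(object@qa))
    if (abs(cf - qaFrac) > 1 / length(object@qa) + 1e-12)
      return("cloudFraction inconsistent with the QA bitmask")
    TRUE
  }
)

#' BandSet: a ten-band reflectance stack with nodata as NA
#'
#' @slot bands numeric array height x width x 10 with dimnames on the third
#'   margin equal to \code{bandNames()}; NA marks nodata.
#' @exportClass BandSet
setClass("BandSet",
  representation(bands = "array"),
  validity = function(object) {
    b <- object@bands
    if (length(dim(b)) != 3L || dim(b)[3] != 10L)
      return("bands must be a height x width x 10 array")
    if (!identical(dimnames(b)[[3]], bandNames()))
      return("third-margin dimnames must equal bandNames()")
    v <- b[!is.na(b)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return("reflectance must be in [0, 1] or NA")
    TRUE
  }
)

#' CompositeImage: the 12-layer per-pixel feature stack
#'
#' Ten median-composited reflectance bands plus NDVI and NDWI, with a
#' provenance count of contributing (clear) scenes per pixel. Pixels with zero
#' clear observations are NA in all 12 layers.
#'
#' @slot features numeric array height x width x 12 with dimnames
#'   \code{stackFeatureNames()}.
#' @slot provenance integer matrix of per-pixel clear-observation counts.
#' @exportClass CompositeImage
setClass("CompositeImage",
  representation(features = "array", provenance = "matrix"),
  validity = function(object) {
    f <- object@features
    if (length(dim(f)) != 3L || dim(f)[3] != 12L)
      return("features must be a height x width x 12 array")
    if (!identical(dimnames(f)[[3]], stackFeatureNames()))
      return("feature dimnames must equal stackFeatureNames()")
    if (!identical(dim(object@provenance), dim(f)[1:2]))
      return("provenance grid must be congruent with the features")
    idx <- f[, , c("NDVI", "NDWI"), drop = FALSE]
    v <- idx[!is.na(idx)]
    if (length(v) && (min(v) < -1 || max(v) > 1))
      return("NDVI/NDWI must lie in [-1, 1] or NA")
    TRUE
  }
)

#' TrainingPolygons: labelled sample polygons
#'
#' Each polygon is a closed ring stored as a two-column (x, y) coordinate
#' matrix in pixel units (origin top-left, x rightwards, y downwards), with a
#' LUCIP class code per polygon. Polygons are pairwise disjoint.
#'
#' @slot polygons list of numeric matrices, each n x 2 with first and last
#'   vertex equal.
#' @slot classCode integer vector, one valid code per polygon.
#' @exportClass TrainingPolygons
setClass("TrainingPolygons",
  representation(polygons = "list", classCode = "integer"),
  validity = function(object) {
    if (length(object@polygons) != length(object@classCode))
      return("one class code per polygon required")
    if (length(object@classCode) && !all(object@classCode %in% 1:7))
      return("class codes must be valid LUCIP codes (1-7)")
    ok <- vapply(object@polygons, function(p)
      is.matrix(p) && ncol(p) == 2L && nrow(p) >= 4L &&
        all(p[1, ] == p[nrow(p), ]), logical(1))
    if (length(ok) && !all(ok))
      return("each polygon must be a closed ring matrix with >= 4 vertices")
    TRUE
  }
)

#' TrainingSet: polygon-sampled training pixels
#'
#' @slot features numeric matrix (rows = pixels, columns = the 12 stack
#'   features), no NA.
#' @slot labels factor of class codes, levels sorted numerically.
#' @slot counts named integer vector of per-class pixel counts.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(features = "matrix", labels = "factor", counts = "integer"),
  validity = function(object) {
    if (nrow(object@features) != length(object@labels))
      return("one label per feature row required")
    if (anyNA(object@features)) return("features must contain no NA")
    if (sum(object@counts) != nrow(object@features))
      return("per-class counts must sum to the row count")
    TRUE
  }
)

#' ForestModel: a trained ensemble-of-decision-trees classifier
#'
#' Wraps the fitted forest together with the training configuration so that
#' prediction and variable importance are reproducible.
#'
#' @slot fit the underlying randomForest fit.
#' @slot nTrees integer, number of trees (>= 1).
#' @slot variablesPerSplit integer in [1, number of features].
#' @slot seed integer training seed.
#' @slot featureNames character vector of training feature names, in order.
#' @exportClass ForestModel
setClass("ForestModel",
  representation(fit = "ANY", nTrees = "integer",
                 variablesPerSplit = "integer", seed = "integer",
                 featureNames = "character"),
  validity = function(object) {
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    if (object@variablesPerSplit < 1L ||
        object@variablesPerSplit > length(object@featureNames))
      return("variablesPerSplit must be in [1, number of features]")
    TRUE
  }
)

#' ConfusionMatrix: stratified validation cross-tabulation
#'
#' Counts n_ij with rows = map class (stratum) and columns = reference class,
#' together with the mapped (pixel-counted) area of each stratum in hectares.
#' The mapped areas supply the stratum weights W_i = A_i / sum(A) used by the
#' area-based error matrix and the unbiased area estimators.
#'
#' @slot counts integer matrix with identical row and column class names.
#' @slot mappedAreasHa named numeric vector of per-stratum mapped areas (ha).
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", mappedAreasHa = "numeric"),
  validity = function(object) {
    cm <- object@counts
    if (nrow(cm) != ncol(cm)) return("counts must be square")
    if (!identical(rownames(cm), colnames(cm)))
      return("row and column class names must match")
    if (any(cm < 0) || any(cm != round(cm)))
      return("counts must be non-negative integers")
    a <- object@mappedAreasHa
    if (!identical(names(a), rownames(cm)))
      return("mappedAreasHa names must match the matrix classes")
    if (any(!is.finite(a)) || any(a < 0))
      return("mapped areas must be finite and non-negative")
    if (any(rowSums(cm) > 0 & a <= 0))
      return("sampled strata must have positive mapped area")
    TRUE
  }
)
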