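#' The LUCIP land-use class schema
#'
#' The seven-class Land Use Classification for Irish Peatlands (LUCIP):
#' cutaway (industrial peat extraction), cutover (domestic extraction),
#' grassland, forestry, remnant peatland (high bog), water bodies and
#' built-up/infrastructure. Class codes 1--7 follow this order everywhere in
#' the package; code 0 is reserved for nodata / outside-mask pixels.
#'
#' @return A data.frame with columns \code{code} (integer 1--7) and
#'   \code{name} (character).
#' @examples
#' lucipClasses()
#' @export
lucipClasses <- function() {
  data.frame(
    code = 1:7,
    name = c("cutaway", "cutover", "grassland", "forestry",
             "remnant_peatland", "water", "built_up"),
    stringsAsFactors = FALSE
  )
}

#' @rdname lucipClasses
#' @param code integer vector of class codes.
#' @return \code{lucipName}: character vector of class names.
#' @export
lucipName <- function(code) {
  tab <- lucipClasses()
  out <- tab$name[match(code, tab$code)]
  if (anyNA(out)) stop("unknown LUCIP class code: ",
                       paste(code[is.na(out)], collapse = ", "))
  out
}

#' @rdname lucipClasses
#' @param name character vector of class names.
#' @return \code{lucipCode}: integer vector of class codes.
#' @export
lucipCode <- function(name) {
  tab <- lucipClasses()
  out <- tab$code[match(name, tab$name)]
  if (anyNA(out)) stop("unknown LUCIP class name: ",
                       paste(name[is.na(out)], collapse = ", "))
  out
}

#' Band names of the ten-band reflectance stack
#'
#' Band order used throughout: Blue (B2), Green (B3), Red (B4), three
#' vegetation red-edge bands (B5, B6, B7), NIR (B8), narrow NIR (B8a) and two
#' SWIR bands (B11 at 1.61 um, B12 at 2.19 um). The native 20 m bands are
#' assumed upsampled to the common 10 m grid (see \code{\link{upsampleNearest}}).
#'
#' @return character vector of length 10.
#' @export
bandNames <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8a", "B11", "B12")
}

#' @rdname bandNames
#' @return \code{stackFeatureNames}: the 12 feature-layer names of a composite
#'   (ten bands plus NDVI and NDWI).
#' @export
stackFeatureNames <- function() {
  c(bandNames(), "NDVI", "NDWI")
}

# QA bitmask convention: bit 10 = opaque cloud, bit 11 = cirrus
# (bit-compatible with the Sentinel-2 QA60 band).
QA_CLOUD_BIT  <- bitwShiftL(1L, 10L)  # 1024
QA_CIRRUS_BIT <- bitwShiftL(1L, 11L)  # 2048

#' QA bitmask constants
#'
#' Bit values used in the QA band: opaque cloud (bit 10, value 1024) and
#' cirrus (bit 11, value 2048), matching the QA60 convention.
#'
#' @return named integer vector with elements \code{cloud} and \code{cirrus}.
#' @export
qaBits <- function() c(cloud = QA_CLOUD_BIT, cirrus = QA_CIRRUS_BIT)

#' Test which QA values flag cloud or cirrus
#'
#' @param qa integer vector or matrix of QA bitmask values.
#' @return logical of the same shape: TRUE where either bit is set.
#' @export
qaIsCloudy <- function(qa) {
  bitwAnd(as.integer(qa), QA_CLOUD_BIT + QA_CIRRUS_BIT) != 0L
}
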