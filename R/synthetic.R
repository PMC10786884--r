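#' Generate a synthetic LUCIP ground-truth class map
#'
#' Synthesises a spatially contiguous seven-class land-use map by seeded
#' region growing: class-labelled seed points are scattered uniformly over the
#' grid (their number set by \code{patchScale}, their class mix by
#' \code{classProportions} under largest-remainder apportionment, with at
#' least one seed for every requested class) and every pixel takes the class
#' of its nearest seed, growth-order ties broken towards the lowest class
#' code. The result mimics a management-unit mosaic rather than
#' salt-and-pepper noise: mean patch size is of order \code{patchScale^2}
#' pixels and realised class shares track the request closely on maps of
#' 200 x 200 pixels and larger.
#'
#' @param width,height grid size in pixels (>= 1).
#' @param classProportions numeric vector of 7 non-negative proportions in
#'   LUCIP code order, summing to 1 (tolerance 1e-9).
#' @param patchScale characteristic patch edge length in pixels (>= 1); the
#'   grid receives roughly \code{width*height/patchScale^2} seeds.
#' @param seed integer RNG seed; identical seeds give bit-identical maps.
#' @param pixelSizeHa pixel area in hectares; default 0.01 (a 10 m pixel).
#' @return a \linkS4class{ClassMap}.
#' @examples
#' m <- generateClassMap(120, 120, c(.1, .11, .43, .21, .13, .01, .01),
#'                       patchScale = 12, seed = 7)
#' classAreasHa(m)
#' @export
generateClassMap <- function(width, height, classProportions,
                             patchScale = 20, seed = 1L,
                             pixelSizeHa = 0.01) {
  if (width < 1L || height < 1L) stop("grid must have positive size")
  p <- classProportions
  if (length(p) != 7L || any(p < 0)) stop("classProportions must be 7 non-negative values")
  if (abs(sum(p) - 1) > 1e-9) stop("classProportions must sum to 1")
  if (patchScale < 1) stop("patchScale must be >= 1")

  set.seed(as.integer(seed))
  n <- width * height
  nSeeds <- max(sum(p > 0), as.integer(ceiling(n / patchScale^2)))
  seedCounts <- largestRemainder(p, nSeeds)
  # Every requested class must appear: take seeds from the best-endowed class.
  short <- which(p > 0 & seedCounts == 0L)
  for (i in short) {
    donor <- which.max(seedCounts)
    seedCounts[donor] <- seedCounts[donor] - 1L
    seedCounts[i] <- 1L
  }
  seedClass <- sample(rep.int(1:7, seedCounts))
  sx <- stats::runif(nSeeds, 0, width)
  sy <- stats::runif(nSeeds, 0, height)

  ctr <- pixelCentres(height, width)
  # order seeds so equal-distance ties resolve to the lowest class code
  o <- order(seedClass)
  best <- rep(Inf, n)
  cls <- rep(0L, n)
  for (i in o) {
    d <- (ctr$x - sx[i])^2 + (ctr$y - sy[i])^2
    upd <- d < best - 1e-12
    best[upd] <- d[upd]
    cls[upd] <- seedClass[i]
  }
  grid <- matrix(cls, nrow = height, ncol = width)
  new("ClassMap", grid = grid, pixelSizeHa = pixelSizeHa)
}

#' Default per-class spectral signatures
#'
#' Fixed ten-band mean reflectances for the seven LUCIP classes, constructed
#' (not measured) to carry the qualitative separability structure of degraded
#' raised-bog land covers on decametric multispectral imagery: built-up is
#' brightest in the visible bands; water is darkest in the NIR; grassland and
#' cutaway have high NIR reflectance; cutover and remnant peatland are the
#' most spectrally similar pair (smallest inter-class Euclidean distance,
#' cutover being a revegetating mosaic); and inter-class contrast in the two
#' SWIR bands is weaker than in the visible/NIR range.
#'
#' @param seed accepted for interface symmetry with the other generators; the
#'   signature set is a fixed constant and the argument is unused.
#' @param noiseSd per-band additive noise standard deviation (reflectance
#'   units); scalar recycled to the 10 bands. Default 0.01.
#' @return a \linkS4class{SpectralSignatureSet}.
#' @export
defaultSignatures <- function(seed = NULL, noiseSd = 0.01) {
  m <- rbind(
    cutaway          = c(0.060, 0.080, 0.100, 0.180, 0.300, 0.380, 0.420, 0.440, 0.180, 0.140),
    cutover          = c(0.050, 0.070, 0.080, 0.140, 0.220, 0.280, 0.310, 0.320, 0.160, 0.130),
    grassland        = c(0.030, 0.060, 0.050, 0.160, 0.320, 0.420, 0.460, 0.480, 0.170, 0.120),
    forestry         = c(0.020, 0.040, 0.030, 0.090, 0.180, 0.240, 0.270, 0.280, 0.120, 0.080),
    remnant_peatland = c(0.045, 0.065, 0.075, 0.135, 0.210, 0.260, 0.270, 0.275, 0.155, 0.125),
    water            = c(0.040, 0.050, 0.030, 0.020, 0.015, 0.012, 0.010, 0.010, 0.020, 0.010),
    built_up         = c(0.220, 0.240, 0.260, 0.280, 0.300, 0.310, 0.320, 0.330, 0.200, 0.170)
  )
  colnames(m) <- bandNames()
  new("SpectralSignatureSet", means = m, noiseSd = rep_len(noiseSd, 10L))
}

# Paint one scene's contiguous cloud field at target fraction f:
# threshold a smoothed Gaussian field at its (1-f) quantile; the most extreme
# 70% of flagged pixels become opaque cloud (bit 10), the fringe cirrus
# (bit 11).
paintClouds <- function(h, w, f, blobScale) {
  qa <- matrix(0L, h, w)
  if (f <= 0) return(qa)
  fld <- smoothNoiseField(h, w, blobScale)
  nCloud <- round(f * h * w)
  if (nCloud == 0L) return(qa)
  o <- order(fld, decreasing = TRUE)
  cloudy <- o[seq_len(nCloud)]
  nOpaque <- ceiling(0.7 * nCloud)
  qa[cloudy[seq_len(nOpaque)]] <- QA_CLOUD_BIT
  if (nOpaque < nCloud)
    qa[cloudy[(nOpaque + 1L):nCloud]] <- QA_CIRRUS_BIT
  qa
}

#' Generate a cloud-contaminated multi-temporal scene series
#'
#' Each scene's reflectance is the truth map's class mean plus independent
#' per-band Gaussian noise, truncated to [0, 1]; nodata pixels of the truth
#' map are NA. Each scene receives an independent, spatially contiguous cloud
#' field (smoothed-noise blobs, not per-pixel speckle) whose realised
#' fraction is drawn uniformly from \code{cloudFractionRange}; QA bits are
#' set exactly where cloud or cirrus was painted. When \code{nScenes >= 5}
#' and the upper bound is <= 0.5, cloud fields are regenerated until every
#' pixel is clear in at least one scene, so the compositor can always produce
#' a gap-free image.
#'
#' @param truth a \linkS4class{ClassMap}.
#' @param sig a \linkS4class{SpectralSignatureSet}.
#' @param nScenes number of scenes (>= 1).
#' @param cloudFractionRange numeric c(lo, hi) within [0, 1], lo <= hi.
#' @param seed integer RNG seed.
#' @param startDate first acquisition date; scenes are spaced 10 days apart.
#' @param blobScale smoothing radius (pixels) of the cloud field; default
#'   scales with the grid.
#' @return list of \linkS4class{Scene} objects.
#' @export
generateSceneSeries <- function(truth, sig, nScenes,
                                cloudFractionRange = c(0, 0.3), seed = 1L,
                                startDate = as.Date("2018-01-01"),
                                blobScale = NULL) {
  stopifnot(is(truth, "ClassMap"), is(sig, "SpectralSignatureSet"))
  if (nScenes < 1L) stop("nScenes must be >= 1")
  r <- cloudFractionRange
  if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 1)
    stop("cloudFractionRange must be c(lo, hi) within [0, 1] with lo <= hi")

  g <- truth@grid
  h <- nrow(g); w <- ncol(g)
  if (is.null(blobScale)) blobScale <- max(3L, round(min(h, w) / 12))
  set.seed(as.integer(seed))

  means <- sig@means
  sds <- sig@noiseSd
  base <- array(NA_real_, c(h, w, 10L))
  ok <- g != 0L
  for (b in 1:10) {
    layer <- matrix(NA_real_, h, w)
    layer[ok] <- means[g[ok], b]
    base[, , b] <- layer
  }

  makeBands <- function() {
    bands <- base
    for (b in 1:10) {
      if (sds[b] > 0)
        bands[, , b] <- bands[, , b] + matrix(stats::rnorm(h * w, 0, sds[b]), h, w)
    }
    bands[bands < 0] <- 0
    bands[bands > 1] <- 1
    bands
  }

  qaList <- vector("list", nScenes)
  for (s in seq_len(nScenes)) {
    f <- stats::runif(1, r[1], r[2])
    qaList[[s]] <- paintClouds(h, w, f, blobScale)
  }
  # coverage guarantee by regeneration
  if (nScenes >= 5L && r[2] <= 0.5) {
    tries <- 0L
    repeat {
      everClear <- Reduce(`|`, lapply(qaList, function(q) q == 0L))
      if (all(everClear) || tries >= 200L) break
      worst <- which.max(vapply(qaList, function(q) mean(q != 0L), numeric(1)))
      f <- stats::runif(1, r[1], r[2])
      qaList[[worst]] <- paintClouds(h, w, f, blobScale)
      tries <- tries + 1L
    }
    everClear <- Reduce(`|`, lapply(qaList, function(q) q == 0L))
    if (!all(everClear))
      stop("could not guarantee a clear observation for every pixel")
  }

  lapply(seq_len(nScenes), function(s) {
    new("Scene",
        bands = makeBands(),
        qa = qaList[[s]],
        date = startDate + (s - 1L) * 10L,
        cloudFraction = mean(qaList[[s]] != 0L))
  })
}

#' Generate labelled training polygons on a truth map
#'
#' Draws, for each class, the requested number of pairwise-disjoint square
#' polygons (\code{polygonSize} x \code{polygonSize} pixels) whose footprint
#' lies entirely within a single-class region of the truth map; each polygon
#' carries that class's code. Placement is uniform over the eligible
#' positions, seeded. Polygon vertex coordinates are in pixel units (origin
#' top-left), so a square covering pixels (r..r+k-1, c..c+k-1) has corners
#' (c-1, r-1) and (c-1+k, r-1+k).
#'
#' @param truth a \linkS4class{ClassMap}.
#' @param nPerClass integer vector of 7 requested polygon counts (LUCIP code
#'   order); zero skips the class.
#' @param polygonSize polygon edge length in pixels (>= 1).
#' @param seed integer RNG seed.
#' @return a \linkS4class{TrainingPolygons}.
#' @export
generateTrainingPolygons <- function(truth, nPerClass, polygonSize = 3L,
                                     seed = 1L) {
  stopifnot(is(truth, "ClassMap"))
  if (length(nPerClass) != 7L || any(nPerClass < 0))
    stop("nPerClass must be 7 non-negative counts")
  k <- as.integer(polygonSize)
  if (k < 1L) stop("polygonSize must be >= 1")
  g <- truth@grid
  h <- nrow(g); w <- ncol(g)
  present <- sort(unique(as.vector(g[g != 0L])))
  missing <- which(nPerClass > 0 & !(1:7 %in% present))
  if (length(missing))
    stop("training polygons unsatisfiable: class absent from map: ",
         paste(lucipName(missing), collapse = ", "))
  if (h < k || w < k) stop("polygonSize exceeds the grid")

  set.seed(as.integer(seed))
  occupied <- matrix(FALSE, h, w)
  polys <- list()
  codes <- integer(0)

  # k x k window purity via 2-D cumulative sums of the class indicator
  windowFull <- function(ind) {
    cs <- apply(apply(ind, 2L, cumsum), 1L, cumsum)  # transposed cumsum grid
    cs <- t(cs)
    S <- function(r, c) ifelse(r < 1 | c < 1, 0, cs[cbind(pmax(r, 1), pmax(c, 1))])
    rr <- rep(seq_len(h - k + 1L), times = w - k + 1L)
    cc <- rep(seq_len(w - k + 1L), each = h - k + 1L)
    tot <- S(rr + k - 1L, cc + k - 1L) - S(rr - 1L, cc + k - 1L) -
      S(rr + k - 1L, cc - 1L) + S(rr - 1L, cc - 1L)
    cbind(rr, cc)[tot == k * k, , drop = FALSE]
  }

  for (cl in 1:7) {
    nReq <- nPerClass[cl]
    if (nReq == 0L) next
    elig <- windowFull(matrix(as.numeric(g == cl), h, w))
    if (nrow(elig) == 0L)
      stop("training polygons unsatisfiable for class ", lucipName(cl),
           ": no pure ", k, "x", k, " window")
    elig <- elig[sample.int(nrow(elig)), , drop = FALSE]
    got <- 0L
    for (i in seq_len(nrow(elig))) {
      r0 <- elig[i, 1L]; c0 <- elig[i, 2L]
      win <- occupied[r0:(r0 + k - 1L), c0:(c0 + k - 1L)]
      if (any(win)) next
      occupied[r0:(r0 + k - 1L), c0:(c0 + k - 1L)] <- TRUE
      x0 <- c0 - 1; y0 <- r0 - 1
      ring <- cbind(x = c(x0, x0 + k, x0 + k, x0, x0),
                    y = c(y0, y0, y0 + k, y0 + k, y0))
      polys[[length(polys) + 1L]] <- ring
      codes <- c(codes, cl)
      got <- got + 1L
      if (got == nReq) break
    }
    if (got < nReq)
      stop("training polygons unsatisfiable for class ", lucipName(cl),
           ": requested ", nReq, ", placed ", got)
  }
  new("TrainingPolygons", polygons = polys, classCode = codes)
}
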