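# Fixtures are built in code; nothing is read from disk except the
# package's own extdata.

# A Scene with constant per-band reflectance and a given QA grid.
makeScene <- function(h, w, values, qa = NULL, date = as.Date("2018-01-01")) {
  values <- rep_len(values, 10L)
  bands <- array(rep(values, each = h * w), c(h, w, 10L))
  if (is.null(qa)) qa <- matrix(0L, h, w)
  new("Scene", bands = bands, qa = qa, date = date,
      cloudFraction = mean(peatluc::qaIsCloudy(qa)))
}

# A Scene whose QA flags exactly n cloud pixels (first n, column-major).
sceneWithCloudCount <- function(h, w, n, values = 0.3) {
  qa <- matrix(0L, h, w)
  if (n > 0) qa[seq_len(n)] <- peatluc::qaBits()["cloud"]
  makeScene(h, w, values, qa)
}

# A BandSet from an h x w x 10 array.
makeBandSet <- function(arr) {
  dimnames(arr) <- list(NULL, NULL, peatluc::bandNames())
  new("BandSet", bands = arr)
}

# A clean 12-layer stack from a single cloud-free scene.
makeStack <- function(scene) buildFeatureStack(list(scene), 1.0)

# Square polygon ring covering pixels rows r0..r0+k-1, cols c0..c0+k-1.
makeSquareRing <- function(r0, c0, k) {
  x0 <- c0 - 1; y0 <- r0 - 1
  cbind(x = c(x0, x0 + k, x0 + k, x0, x0),
        y = c(y0, y0, y0 + k, y0 + k, y0))
}

makePolygons <- function(rings, codes) {
  new("TrainingPolygons", polygons = rings, classCode = as.integer(codes))
}

# The two-stratum worked confusion matrix: W = (0.8, 0.2) on 1000 ha,
# row counts (45,5) and (10,40) of 50 points each.
workedConfusion <- function() {
  confusionMatrixFromCounts(
    matrix(c(45L, 5L, 10L, 40L), 2L, 2L, byrow = TRUE,
           dimnames = list(c("1", "2"), c("1", "2"))),
    c(800, 200))
}

# A small truth map with all seven classes present.
smallTruth <- function(n = 120L, seed = 99L, patchScale = 12) {
  generateClassMap(n, n, c(.10, .11, .43, .21, .13, .01, .01),
                   patchScale = patchScale, seed = seed)
}

# Equal class shares: every class has room for training polygons even on
# small grids.
uniformTruth <- function(n = 80L, seed = 99L, patchScale = 14) {
  generateClassMap(n, n, rep(1 / 7, 7), patchScale = patchScale, seed = seed)
}
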