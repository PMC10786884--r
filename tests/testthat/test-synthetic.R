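test_that("degenerate proportions give a single-class map and seeds are reproducible", {
  m <- generateClassMap(40, 30, c(1, 0, 0, 0, 0, 0, 0), patchScale = 5, seed = 2)
  expect_true(all(classGrid(m) == 1L))
  expect_identical(dim(classGrid(m)), c(30L, 40L))

  m1 <- generateClassMap(60, 60, rep(1 / 7, 7), patchScale = 8, seed = 11)
  m2 <- generateClassMap(60, 60, rep(1 / 7, 7), patchScale = 8, seed = 11)
  expect_identical(classGrid(m1), classGrid(m2))
})

test_that("class map inputs are validated", {
  expect_error(generateClassMap(50, 50, rep(0.2, 7)), "sum to 1")
  expect_error(generateClassMap(0, 50, c(1, rep(0, 6))), "positive size")
  expect_error(generateClassMap(50, 50, c(1.5, -0.5, rep(0, 5))),
               "non-negative")
})

test_that("realised class shares track the request on a large map", {
  req <- c(0.10, 0.11, 0.43, 0.21, 0.13, 0.01, 0.01)
  m <- generateClassMap(500, 500, req, patchScale = 20, seed = 7)
  shares <- as.numeric(table(factor(classGrid(m), levels = 1:7))) / 250000
  expect_true(all(abs(shares - req) <= 0.05))
})

test_that("classes form contiguous patches, not salt-and-pepper noise", {
  ps <- 10
  m <- generateClassMap(200, 200, rep(1 / 7, 7), patchScale = ps, seed = 5)
  nPatch <- peatluc:::countPatches(classGrid(m))
  meanPatch <- 200 * 200 / nPatch
  expect_gte(meanPatch, ps^2 / 4)
})

test_that("default signatures satisfy the qualitative separability contract", {
  sig <- defaultSignatures()
  m <- signatureMeans(sig)
  expect_identical(dim(m), c(7L, 10L))
  expect_true(all(m >= 0 & m <= 1))

  vis <- c("B2", "B3", "B4")
  expect_true(all(m["built_up", vis] > apply(m[-7, vis, drop = FALSE], 2, max)))
  expect_lt(m["water", "B8"], min(m[rownames(m) != "water", "B8"]))
  expect_true(all(m[c("grassland", "cutaway"), "B8"] >
                    max(m[c("cutover", "forestry", "remnant_peatland",
                            "water"), "B8"])))

  d <- as.matrix(dist(m))
  diag(d) <- Inf
  closest <- arrayInd(which.min(d), dim(d))
  expect_setequal(rownames(m)[as.vector(closest)],
                  c("cutover", "remnant_peatland"))

  # SWIR inter-class contrast weaker than visible/NIR contrast
  meanPairDiff <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    mean(vapply(seq_len(ncol(sub)), function(j)
      mean(as.matrix(dist(sub[, j]))), numeric(1)))
  }
  expect_lt(meanPairDiff(c("B11", "B12")),
            meanPairDiff(c("B2", "B3", "B4", "B8", "B8a")))

  # every pair separated by > 3 x noise SD in at least one visible/NIR band
  vn <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8a")
  thr <- 3 * max(noiseSd(sig))
  for (i in 1:6) for (j in (i + 1):7)
    expect_gt(max(abs(m[i, vn] - m[j, vn])), thr)
})

test_that("nearest-mean classification of noiseless scenes recovers the truth", {
  truth <- smallTruth(80)
  sig <- defaultSignatures(noiseSd = 0)
  sc <- generateSceneSeries(truth, sig, 1, c(0, 0), seed = 3)[[1]]
  m <- signatureMeans(sig)
  h <- nrow(classGrid(truth))
  feat <- matrix(sceneBands(sc), ncol = 10L)
  d2 <- vapply(1:7, function(cl)
    rowSums(sweep(feat, 2, m[cl, ])^2), numeric(nrow(feat)))
  pred <- max.col(-d2, ties.method = "first")
  expect_identical(as.integer(pred), as.vector(classGrid(truth)))
})

test_that("scene series honours cloud range, noise and the QA contract", {
  truth <- smallTruth(60)
  sig <- defaultSignatures()

  clear <- generateSceneSeries(truth, sig, 3, c(0, 0), seed = 1)
  expect_true(all(vapply(clear, function(s) all(sceneQA(s) == 0L), logical(1))))

  noiseless <- generateSceneSeries(truth, defaultSignatures(noiseSd = 0),
                                   1, c(0, 0), seed = 1)[[1]]
  g <- classGrid(truth)
  m <- signatureMeans(sig)
  for (b in c(1L, 7L, 10L))
    expect_equal(sceneBands(noiseless)[, , b],
                 matrix(m[g, b], nrow(g), ncol(g)))

  series <- generateSceneSeries(truth, sig, 10, c(0.05, 0.4), seed = 3)
  fr <- vapply(series, cloudFraction, numeric(1))
  expect_true(all(fr >= 0.05 - 1e-9 & fr <= 0.4 + 1e-9))
  for (s in series)
    expect_equal(cloudFraction(s), mean(qaIsCloudy(sceneQA(s))))

  expect_error(generateSceneSeries(truth, sig, 3, c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("every pixel is clear in at least one scene under the coverage guarantee", {
  truth <- smallTruth(60)
  series <- generateSceneSeries(truth, defaultSignatures(), 5, c(0.3, 0.5),
                                seed = 17)
  everClear <- Reduce(`|`, lapply(series, function(s) sceneQA(s) == 0L))
  expect_true(all(everClear))
})

test_that("scene series is deterministic under the seed", {
  truth <- smallTruth(50)
  a <- generateSceneSeries(truth, defaultSignatures(), 4, c(0.1, 0.3), seed = 8)
  b <- generateSceneSeries(truth, defaultSignatures(), 4, c(0.1, 0.3), seed = 8)
  for (i in seq_along(a)) {
    expect_identical(sceneBands(a[[i]]), sceneBands(b[[i]]))
    expect_identical(sceneQA(a[[i]]), sceneQA(b[[i]]))
  }
})

test_that("training polygons are pure, disjoint and match the requested counts", {
  truth <- smallTruth(150, patchScale = 15)
  tp <- generateTrainingPolygons(truth, rep(1L, 7L), polygonSize = 3, seed = 4)
  expect_length(polygonRings(tp), 7L)
  expect_setequal(polygonClass(tp), 1:7)

  tp2 <- generateTrainingPolygons(truth, c(5L, 5L, 8L, 6L, 5L, 2L, 2L),
                                  polygonSize = 3, seed = 4)
  g <- classGrid(truth)
  covered <- matrix(FALSE, nrow(g), ncol(g))
  for (i in seq_along(polygonRings(tp2))) {
    ring <- polygonRings(tp2)[[i]]
    cols <- (min(ring[, 1]) + 1):max(ring[, 1])
    rows <- (min(ring[, 2]) + 1):max(ring[, 2])
    # purity: every covered pixel carries the polygon's class
    expect_true(all(g[rows, cols] == polygonClass(tp2)[i]))
    # disjointness
    expect_false(any(covered[rows, cols]))
    covered[rows, cols] <- TRUE
  }
})

test_that("a national-scale polygon request is satisfied in full", {
  truth <- generateClassMap(300, 300, rep(1 / 7, 7), patchScale = 25, seed = 21)
  req <- c(37L, 45L, 32L, 100L, 62L, 64L, 26L)
  tp <- generateTrainingPolygons(truth, req, polygonSize = 3, seed = 2)
  expect_length(polygonRings(tp), 366L)
  expect_equal(as.integer(table(factor(polygonClass(tp), levels = 1:7))), req)
})

test_that("polygon requests for absent classes are reported unsatisfiable", {
  truth <- generateClassMap(50, 50, c(0.5, 0.5, 0, 0, 0, 0, 0),
                            patchScale = 10, seed = 1)
  expect_error(generateTrainingPolygons(truth, c(1L, 1L, 1L, rep(0L, 4))),
               "unsatisfiable.*grassland")
})
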