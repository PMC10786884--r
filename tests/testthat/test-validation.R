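test_that("stratified allocation applies the floor-plus-proportional rule", {
  eq <- allocateStratifiedSample(c(a = 10, b = 10, c = 10), 99,
                                 minPerStratum = 0)
  expect_equal(as.integer(eq), c(33L, 33L, 33L))

  worked <- allocateStratifiedSample(c(big = 800, mid = 150, small = 50),
                                     100, minPerStratum = 10)
  expect_equal(as.integer(worked), c(76L, 14L, 10L))

  expect_error(allocateStratifiedSample(c(a = 1, b = 1), 10,
                                        minPerStratum = 10), "infeasible")
})

test_that("allocation conserves the total for arbitrary inputs", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:7, 1)
    areas <- stats::setNames(runif(k, 1, 100), paste0("c", 1:k))
    n <- sample(seq(k * 10, 500), 1)
    alloc <- allocateStratifiedSample(areas, n, minPerStratum = 10)
    expect_equal(sum(alloc), n)
    expect_true(all(alloc >= 10))
  }
})

test_that("validation points are stratified, seeded and label-consistent", {
  truth <- smallTruth(100)
  alloc <- stats::setNames(rep(1L, 7L), 1:7)
  pts <- drawValidationPoints(truth, alloc, seed = 4)
  expect_equal(nrow(pts), 7L)
  expect_setequal(pts$mapClass, 1:7)

  alloc2 <- allocateStratifiedSample(classAreasHa(truth), 200,
                                     minPerStratum = 10)
  p1 <- drawValidationPoints(truth, alloc2, seed = 9)
  p2 <- drawValidationPoints(truth, alloc2, seed = 9)
  expect_identical(p1, p2)
  expect_equal(classGrid(truth)[cbind(p1$row, p1$col)], p1$mapClass)

  tiny <- stats::setNames(c(rep(0L, 5), 100000L, 0L), 1:7)
  expect_error(drawValidationPoints(truth, tiny), "water")
})

test_that("reference labelling simulates interpreter error at the given rate", {
  truth <- smallTruth(100)
  alloc <- allocateStratifiedSample(classAreasHa(truth), 400,
                                    minPerStratum = 20)
  pts <- drawValidationPoints(truth, alloc, seed = 1)
  clean <- simulateReferenceLabels(pts, truth, errorRate = 0)
  expect_equal(clean$refClass, classGrid(truth)[cbind(pts$row, pts$col)])

  noisy <- simulateReferenceLabels(pts, truth, errorRate = 0.3, seed = 2)
  flipped <- mean(noisy$refClass != clean$refClass)
  expect_gt(flipped, 0.15)
  expect_lt(flipped, 0.45)
  expect_true(all(noisy$refClass %in% 1:7))
})

test_that("confusion matrices cross-tabulate and validate labels", {
  lbl <- c(1L, 2L, 2L, 3L, 7L)
  cm <- buildConfusionMatrix(lbl, lbl, stats::setNames(rep(10, 7), 1:7))
  expect_equal(sum(confusionCounts(cm)), 5L)
  expect_equal(sum(diag(confusionCounts(cm))), 5L)

  expect_error(buildConfusionMatrix(integer(0), integer(0), c("1" = 1)),
               "empty")
  expect_error(buildConfusionMatrix(c(1L, 9L), c(1L, 1L), c("1" = 1)),
               "unknown class")
  expect_error(buildConfusionMatrix(1L, c(1L, 2L), c("1" = 1)), "equal length")
})

test_that("accuracy statistics follow the OA/UA/PA definitions", {
  counts <- packagedValidationCounts()
  cm <- confusionMatrixFromCounts(counts, rep(1000, 7))
  expect_equal(as.integer(rowSums(confusionCounts(cm))),
               c(197L, 130L, 50L, 252L, 660L, 121L, 50L))
  expect_equal(sum(confusionCounts(cm)), 1460L)

  acc <- accuracyReport(cm)
  expect_equal(acc$oa, 100 * 1303 / 1460)
  expect_equal(acc$correct, 1303L)
  disp <- formatAccuracy(acc)
  expect_equal(disp$UA[disp$class == "cutover"], 70)
  expect_equal(disp$PA[disp$class == "cutaway"], 97)
  expect_equal(disp$UA[disp$class == "forestry"], 96)  # 244/252 truncates

  # zero row/column totals give undefined (NA), not zero
  m <- matrix(c(5L, 0L, 0L, 0L), 2, 2, dimnames = list(1:2, 1:2))
  cm0 <- confusionMatrixFromCounts(m, c(10, 0))
  acc0 <- accuracyReport(cm0)
  expect_true(is.na(acc0$ua["2"]))
  expect_true(is.na(acc0$pa["2"]))
})

test_that("the area-based error matrix applies stratified weights", {
  # diagonal matrix: p_ii = W_i
  d <- confusionMatrixFromCounts(diag(c(10L, 20L, 30L)), c(100, 300, 600))
  p <- areaErrorMatrix(d)
  expect_equal(diag(p), c("1" = 0.1, "2" = 0.3, "3" = 0.6))
  expect_equal(sum(p), 1)

  pw <- areaErrorMatrix(workedConfusion())
  expect_equal(unname(pw), matrix(c(0.72, 0.08, 0.04, 0.16), 2, byrow = TRUE))
  expect_equal(sum(pw), 1)
})

test_that("unbiased area estimates match the hand-computed oracle", {
  est <- unbiasedAreaEstimates(workedConfusion())
  expect_equal(est$areaHa[1], 760)
  seOracle <- sqrt((0.64 * 0.09 + 0.04 * 0.16) / 49) * 1000
  expect_equal(est$seHa[1], seOracle, tolerance = 1e-12)
  expect_equal(est$ciLowHa[1], 760 - 1.96 * seOracle)
  expect_equal(sum(est$propRef), 1)

  # perfect-map limit: estimates collapse to the mapped areas with zero SE
  d <- confusionMatrixFromCounts(diag(c(10L, 20L, 30L)), c(100, 300, 600))
  estD <- unbiasedAreaEstimates(d)
  expect_equal(estD$areaHa, c(100, 300, 600))
  expect_equal(estD$seHa, c(0, 0, 0))

  # single-point stratum: SE undefined
  one <- confusionMatrixFromCounts(matrix(c(1L, 0L, 0L, 5L), 2, byrow = TRUE),
                                   c(10, 50))
  expect_error(unbiasedAreaEstimates(one), "single point")
})

test_that("count-based and area-weighted OA are distinct but consistent", {
  cm <- workedConfusion()
  accOA <- accuracyReport(cm)$oa
  areaOA <- areaWeightedOA(cm)
  # direct recomputation of the weighted form
  expect_equal(areaOA, 100 * (0.8 * 45 / 50 + 0.2 * 40 / 50))
  expect_equal(accOA, 100 * 85 / 100)
  expect_false(isTRUE(all.equal(accOA, areaOA)))
})

test_that("zonal tabulation recounts class areas by region", {
  truth <- smallTruth(60)
  h <- nrow(classGrid(truth)); w <- ncol(classGrid(truth))
  whole <- list(all = makeSquareRing(1, 1, 60))
  tab <- zonalTabulate(truth, whole)
  glob <- classAreasHa(truth)
  expect_equal(as.numeric(tab[1, lucipClasses()$name]), unname(glob))
  expect_equal(tab$total, 60 * 60 * 0.01)

  # a two-region split recounted by hand against the grid
  left <- makeSquareRing(1, 1, 30)
  regions <- list(west = left,
                  east = cbind(x = c(30, 60, 60, 30, 30),
                               y = c(0, 0, 60, 60, 0)))
  tab2 <- zonalTabulate(truth, regions)
  g <- classGrid(truth)
  handWest <- tabulate(factor(g[1:30, 1:30], levels = 1:7), 7) * 0.01
  expect_equal(as.numeric(tab2[1, lucipClasses()$name]), handWest)
  expect_true(all(colSums(tab2[, lucipClasses()$name]) <= unname(glob) + 1e-12))

  expect_warning(zonalTabulate(truth, list(off = makeSquareRing(200, 200, 5))),
                 "no pixel centre")
})

test_that("the area estimator is jointly unbiased over repeated stratified sampling", {
  # fixed truth, fixed imperfect map, 500 resampled validation draws; the
  # seven standardised mean deviations are jointly chi-square distributed
  # when the estimator is unbiased
  truth <- generateClassMap(150, 150, c(.10, .11, .43, .21, .13, .01, .01),
                            patchScale = 15, seed = 301)
  g <- classGrid(truth)
  set.seed(302)
  flip <- sample(length(g), round(0.10 * length(g)))
  mg <- g
  mg[flip] <- vapply(g[flip], function(cl) sample(setdiff(1:7, cl), 1L),
                     integer(1))
  map <- new("ClassMap", grid = mg, pixelSizeHa = 0.01)
  mapped <- classAreasHa(map)
  trueAreas <- classAreasHa(truth)
  alloc <- allocateStratifiedSample(mapped, 700, minPerStratum = 50)
  nRep <- 500
  estA <- matrix(NA_real_, nRep, 7)
  for (r in seq_len(nRep)) {
    pts <- drawValidationPoints(map, alloc, seed = r)
    pts <- simulateReferenceLabels(pts, truth, errorRate = 0)
    cm <- buildConfusionMatrix(pts$mapClass, pts$refClass, mapped)
    estA[r, ] <- unbiasedAreaEstimates(cm)$areaHa
  }
  z <- (colMeans(estA) - trueAreas) / (apply(estA, 2, sd) / sqrt(nRep))
  expect_lt(sum(z^2), qchisq(0.999, df = 7))
})
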