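test_that("training-pixel extraction counts pixels by centre containment", {
  sc <- makeScene(10, 10, seq(0.1, 0.55, length.out = 10))
  stack <- makeStack(sc)
  tp <- makePolygons(list(makeSquareRing(3, 4, 3)), 2L)
  ts <- extractTrainingPixels(stack, tp)
  expect_equal(nrow(trainingFeatures(ts)), 9L)
  expect_true(all(trainingLabels(ts) == "2"))

  # a 2-pixel nodata hole inside the polygon drops exactly those rows
  stack2 <- stack
  stack2@features[3, 4, ] <- NA
  stack2@features[4, 5, ] <- NA
  tp2 <- makePolygons(list(makeSquareRing(3, 4, 3), makeSquareRing(8, 1, 2)),
                      c(2L, 5L))
  ts2 <- extractTrainingPixels(stack2, tp2)
  expect_equal(as.integer(classCounts(ts2)), c(7L, 4L))

  # a class reduced to zero usable pixels is a named error
  stack3 <- stack
  stack3@features[8:9, 1:2, ] <- NA
  expect_error(extractTrainingPixels(stack3, tp2), "remnant_peatland")
})

test_that("per-class extracted counts equal the rasterised polygon areas", {
  truth <- smallTruth(100)
  series <- generateSceneSeries(truth, defaultSignatures(), 5, c(0, 0.2),
                                seed = 3)
  stack <- buildFeatureStack(series, 1.0)
  req <- c(3L, 3L, 5L, 4L, 3L, 2L, 2L)
  tp <- generateTrainingPolygons(truth, req, polygonSize = 3, seed = 12)
  ts <- extractTrainingPixels(stack, tp)
  expect_equal(as.integer(classCounts(ts)), req * 9L)
})

test_that("a single-threshold two-class problem is learned perfectly", {
  set.seed(5)
  n <- 200
  x <- matrix(runif(n * 12), n, 12, dimnames = list(NULL, stackFeatureNames()))
  y <- ifelse(x[, "B8"] > 0.5, 3L, 6L)
  x[, "B8"] <- ifelse(y == 3L, runif(n, 0.7, 1), runif(n, 0, 0.3))
  ts <- new("TrainingSet", features = x,
            labels = factor(y, levels = c(3L, 6L)),
            counts = stats::setNames(as.integer(table(factor(y, c(3, 6)))),
                                     c("3", "6")))
  model <- trainForest(ts, nTrees = 20, seed = 1)
  votes <- predict(model@fit, x, type = "response")
  expect_equal(as.integer(as.character(votes)), as.integer(y))
})

test_that("forest training validates its inputs and degenerates gracefully", {
  x <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  y1 <- factor(rep(1L, 30), levels = "1")
  ts1 <- new("TrainingSet", features = x, labels = y1,
             counts = c("1" = 30L))
  expect_error(trainForest(ts1), "single class")

  y2 <- factor(rep(c(1L, 2L), 15))
  ts2 <- new("TrainingSet", features = x, labels = y2,
             counts = c("1" = 15L, "2" = 15L))
  expect_error(trainForest(ts2, nTrees = 0), "nTrees")
  expect_error(trainForest(ts2, variablesPerSplit = 5), "variablesPerSplit")

  single <- trainForest(ts2, nTrees = 1, variablesPerSplit = 2, seed = 3)
  expect_equal(single@nTrees, 1L)
  expect_equal(single@variablesPerSplit, 2L)
})

test_that("training is deterministic under the seed", {
  truth <- smallTruth(60)
  series <- generateSceneSeries(truth, defaultSignatures(), 5, c(0, 0.2),
                                seed = 3)
  stack <- buildFeatureStack(series, 1.0)
  tp <- generateTrainingPolygons(truth, rep(3L, 7L), polygonSize = 3, seed = 2)
  ts <- extractTrainingPixels(stack, tp)
  m1 <- trainForest(ts, seed = 77)
  m2 <- trainForest(ts, seed = 77)
  p1 <- predictMap(m1, stack)
  p2 <- predictMap(m2, stack)
  expect_identical(classGrid(p1), classGrid(p2))
})

test_that("prediction recovers the truth on noiseless separable data", {
  truth <- uniformTruth(80)
  sc <- generateSceneSeries(truth, defaultSignatures(noiseSd = 0), 1,
                            c(0, 0), seed = 1)
  stack <- buildFeatureStack(sc, 1.0)
  tp <- generateTrainingPolygons(truth, rep(4L, 7L), polygonSize = 3, seed = 5)
  model <- trainForest(extractTrainingPixels(stack, tp), seed = 10)
  map <- predictMap(model, stack)
  expect_equal(mean(classGrid(map) == classGrid(truth)), 1.0)
})

test_that("nodata pixels predict to the nodata class", {
  sc <- makeScene(6, 6, seq(0.1, 0.55, length.out = 10))
  stack <- makeStack(sc)
  tp <- makePolygons(list(makeSquareRing(1, 1, 2), makeSquareRing(4, 4, 2)),
                     c(1L, 2L))
  # make the two polygons spectrally distinct
  stack@features[4:5, 4:5, "B8"] <- 0.9
  model <- trainForest(extractTrainingPixels(stack, tp), nTrees = 5, seed = 1)

  allNA <- stack
  allNA@features[] <- NA_real_
  expect_true(all(classGrid(predictMap(model, allNA)) == 0L))

  hole <- stack
  hole@features[1, 6, ] <- NA
  map <- predictMap(model, hole)
  expect_equal(classGrid(map)[1, 6], 0L)
  expect_equal(sum(classGrid(map) == 0L), 1L)
})

test_that("plurality voting matches a direct recount with lowest-code ties", {
  truth <- uniformTruth(48)
  series <- generateSceneSeries(truth, defaultSignatures(noiseSd = 0.05), 3,
                                c(0, 0), seed = 2)
  stack <- buildFeatureStack(series, 1.0)
  tp <- generateTrainingPolygons(truth, rep(3L, 7L), polygonSize = 3, seed = 2)
  model <- trainForest(extractTrainingPixels(stack, tp), nTrees = 4, seed = 9)
  map <- predictMap(model, stack)

  feat <- matrix(stackFeatures(stack), ncol = 12,
                 dimnames = list(NULL, stackFeatureNames()))
  ok <- !is.na(rowSums(feat))   # degenerate-index pixels are nodata
  votes <- predict(model@fit, feat[ok, , drop = FALSE], type = "vote",
                   norm.votes = FALSE)
  expect_true(all(rowSums(votes) == 4))  # vote conservation
  codes <- as.integer(colnames(votes))
  manual <- vapply(seq_len(nrow(votes)), function(i) {
    v <- votes[i, ]
    codes[which(v == max(v))[1]]  # lowest class code among tied maxima
  }, integer(1))
  expect_identical(as.vector(classGrid(map))[ok], manual)
  expect_true(all(as.vector(classGrid(map))[!ok] == 0L))
})

test_that("map accuracy degrades monotonically with reflectance noise", {
  truth <- smallTruth(60)
  agree <- vapply(c(0.01, 0.08, 0.2), function(sd) {
    sig <- defaultSignatures(noiseSd = sd)
    series <- generateSceneSeries(truth, sig, 5, c(0, 0), seed = 31)
    stack <- buildFeatureStack(series, 1.0)
    tp <- generateTrainingPolygons(truth, rep(4L, 7L), polygonSize = 3,
                                   seed = 6)
    model <- trainForest(extractTrainingPixels(stack, tp), seed = 14)
    mean(classGrid(predictMap(model, stack)) == classGrid(truth))
  }, numeric(1))
  expect_true(all(diff(agree) <= 0))
})

test_that("variable importance identifies informative and noise features", {
  set.seed(8)
  n <- 300
  x <- matrix(runif(n * 12), n, 12, dimnames = list(NULL, stackFeatureNames()))
  y <- sample(c(1L, 4L), n, replace = TRUE)
  x[, "NDVI"] <- ifelse(y == 1L, runif(n, 0.6, 1), runif(n, -1, 0.2))
  ts <- new("TrainingSet", features = x,
            labels = factor(y, levels = c(1L, 4L)),
            counts = stats::setNames(as.integer(table(factor(y, c(1, 4)))),
                                     c("1", "4")))
  model <- trainForest(ts, nTrees = 30, seed = 2)
  imp <- variableImportance(model)
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$feature[imp$rank == 1], "NDVI")
  expect_true(all(imp$importance >= 0))
  expect_setequal(imp$feature, stackFeatureNames())
})

test_that("feature mismatch between stack and model is rejected", {
  sc <- makeScene(6, 6, seq(0.1, 0.55, length.out = 10))
  stack <- makeStack(sc)
  stack@features[1:3, , "B8"] <- 0.9
  tp <- makePolygons(list(makeSquareRing(1, 1, 2), makeSquareRing(5, 5, 2)),
                     c(1L, 2L))
  model <- trainForest(extractTrainingPixels(stack, tp), nTrees = 3, seed = 1)
  model@featureNames <- rev(model@featureNames)
  expect_error(predictMap(model, stack), "feature layers")
})
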