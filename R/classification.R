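#' Extract training pixels from a feature stack using labelled polygons
#'
#' One training row per non-nodata pixel whose centre falls inside a polygon
#' (pixel-centre containment, even-odd rule); the row's label is the
#' polygon's class code. Rows with any nodata feature are dropped, not
#' imputed. A requested class that yields zero rows is an error naming the
#' class.
#'
#' @param stack a \linkS4class{CompositeImage}.
#' @param polygons a \linkS4class{TrainingPolygons}.
#' @return a \linkS4class{TrainingSet}.
#' @export
extractTrainingPixels <- function(stack, polygons) {
  stopifnot(is(stack, "CompositeImage"), is(polygons, "TrainingPolygons"))
  f <- stack@features
  h <- dim(f)[1]; w <- dim(f)[2]
  featMat <- matrix(f, nrow = h * w, ncol = 12L,
                    dimnames = list(NULL, stackFeatureNames()))
  rows <- integer(0); labs <- integer(0)
  for (i in seq_along(polygons@polygons)) {
    ring <- polygons@polygons[[i]]
    cl <- polygons@classCode[i]
    c0 <- max(1L, floor(min(ring[, 1])) + 1L)
    c1 <- min(w, ceiling(max(ring[, 1])))
    r0 <- max(1L, floor(min(ring[, 2])) + 1L)
    r1 <- min(h, ceiling(max(ring[, 2])))
    if (c1 < c0 || r1 < r0) next
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    inside <- pointsInRing(cc - 0.5, rr - 0.5, ring)
    idx <- (cc[inside] - 1L) * h + rr[inside]
    rows <- c(rows, idx)
    labs <- c(labs, rep.int(cl, sum(inside)))
  }
  keep <- !is.na(rowSums(featMat[rows, , drop = FALSE]))
  rows <- rows[keep]; labs <- labs[keep]
  requested <- sort(unique(polygons@classCode))
  got <- requested %in% labs
  if (!all(got))
    stop("no usable training pixels for class: ",
         paste(lucipName(requested[!got]), collapse = ", "))
  labels <- factor(labs, levels = sort(unique(labs)))
  counts <- as.integer(table(labels))
  names(counts) <- levels(labels)
  new("TrainingSet",
      features = featMat[rows, , drop = FALSE],
      labels = labels, counts = counts)
}

#' Train the ensemble-of-decision-trees classifier
#'
#' Trains a random forest: each tree is grown on a bootstrap resample of the
#' training rows (sample size = training size), choosing among
#' \code{variablesPerSplit} randomly drawn features at each split under the
#' Gini impurity criterion, with unlimited depth and minimum leaf size 1.
#' \code{"sqrt"} resolves to \code{floor(sqrt(nFeatures))}, i.e. 3 of the 12
#' stack features. Identical data and seed give an identical model.
#'
#' @param data a \linkS4class{TrainingSet} with at least two classes.
#' @param nTrees number of trees (default 20).
#' @param variablesPerSplit integer, or \code{"sqrt"} (the default).
#' @param seed integer training seed.
#' @return a \linkS4class{ForestModel}.
#' @export
trainForest <- function(data, nTrees = 20L, variablesPerSplit = "sqrt",
                        seed = 1L) {
  stopifnot(is(data, "TrainingSet"))
  if (nTrees < 1L) stop("nTrees must be >= 1")
  if (nlevels(droplevels(data@labels)) < 2L)
    stop("training data contains a single class; at least two are required")
  p <- ncol(data@features)
  mtry <- if (identical(variablesPerSplit, "sqrt")) {
    as.integer(floor(sqrt(p)))
  } else {
    as.integer(variablesPerSplit)
  }
  if (mtry < 1L || mtry > p)
    stop("variablesPerSplit must be in [1, ", p, "]")
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = data@features, y = droplevels(data@labels),
    ntree = as.integer(nTrees), mtry = mtry,
    nodesize = 1, replace = TRUE, importance = FALSE
  )
  new("ForestModel", fit = fit, nTrees = as.integer(nTrees),
      variablesPerSplit = mtry, seed = as.integer(seed),
      featureNames = colnames(data@features))
}

#' Predict a class map from a feature stack
#'
#' Every tree votes per pixel; the plurality label wins, with ties among the
#' vote counts broken towards the lowest class code. Pixels with any nodata
#' feature are nodata (code 0) in the output map.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param stack a \linkS4class{CompositeImage} whose feature layers match the
#'   training features in order.
#' @param pixelSizeHa pixel area of the output map in hectares.
#' @return a \linkS4class{ClassMap}.
#' @export
predictMap <- function(model, stack, pixelSizeHa = 0.01) {
  stopifnot(is(model, "ForestModel"), is(stack, "CompositeImage"))
  f <- stack@features
  if (!identical(dimnames(f)[[3]], model@featureNames))
    stop("feature layers do not match the model's training features")
  h <- dim(f)[1]; w <- dim(f)[2]
  featMat <- matrix(f, nrow = h * w, ncol = 12L,
                    dimnames = list(NULL, model@featureNames))
  ok <- !is.na(rowSums(featMat))
  out <- rep(0L, h * w)
  if (any(ok)) {
    votes <- stats::predict(model@fit, featMat[ok, , drop = FALSE],
                            type = "vote", norm.votes = FALSE)
    # columns are factor levels = class codes in increasing order, so
    # ties.method = "first" realises the lowest-code tie-break
    winner <- max.col(votes, ties.method = "first")
    out[ok] <- as.integer(colnames(votes))[winner]
  }
  new("ClassMap", grid = matrix(out, h, w), pixelSizeHa = pixelSizeHa)
}

#' Variable importance of the trained forest
#'
#' Mean-decrease-in-impurity (Gini) importance per feature, normalised to
#' sum to 1, with the rank order (1 = most important; ties share the
#' smallest rank).
#'
#' @param model a \linkS4class{ForestModel}.
#' @return data.frame with columns \code{feature}, \code{importance},
#'   \code{rank}, ordered by decreasing importance.
#' @export
variableImportance <- function(model) {
  stopifnot(is(model, "ForestModel"))
  imp <- randomForest::importance(model@fit, type = 2)[, 1]
  tot <- sum(imp)
  score <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  out <- data.frame(feature = names(score), importance = as.numeric(score),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "min")
  out[order(out$rank, out$feature), , drop = FALSE]
}

#' Serialise a forest model to a documented JSON tree structure
#'
#' Writes one record per tree; each record lists its nodes with
#' \code{left}/\code{right} daughter indices, split feature name, split
#' threshold (left branch takes values <= threshold) and, for terminal
#' nodes, the leaf class code.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeForestJSON <- function(model, path) {
  stopifnot(is(model, "ForestModel"))
  codes <- as.integer(levels(model@fit$y))
  trees <- lapply(seq_len(model@nTrees), function(k) {
    tr <- randomForest::getTree(model@fit, k, labelVar = FALSE)
    data.frame(
      left = tr[, "left daughter"],
      right = tr[, "right daughter"],
      feature = ifelse(tr[, "status"] == -1, NA_character_,
                       model@featureNames[tr[, "split var"]]),
      threshold = ifelse(tr[, "status"] == -1, NA_real_,
                         tr[, "split point"]),
      leafClass = ifelse(tr[, "status"] == -1, codes[tr[, "prediction"]],
                         NA_integer_),
      stringsAsFactors = FALSE
    )
  })
  obj <- list(nTrees = model@nTrees,
              variablesPerSplit = model@variablesPerSplit,
              seed = model@seed,
              features = model@featureNames,
              trees = trees)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
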