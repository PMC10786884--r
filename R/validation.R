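#' Stratified validation sample allocation
#'
#' Allocates \code{totalN} validation points across map strata proportionally
#' to mapped area, with a per-stratum floor: strata whose proportional share
#' falls below \code{minPerStratum} are pinned at the floor and the remaining
#' points are re-apportioned proportionally among the others
#' (largest-remainder rounding makes the counts sum exactly to
#' \code{totalN}). The rule is deterministic; \code{seed} is accepted for
#' interface symmetry and unused.
#'
#' @param mappedAreasHa named numeric vector of per-class mapped areas (ha);
#'   zero-area classes receive no points.
#' @param totalN total number of validation points.
#' @param minPerStratum per-stratum floor (applied to mapped classes).
#' @param seed unused.
#' @return named integer vector of per-class counts summing to
#'   \code{totalN}.
#' @export
allocateStratifiedSample <- function(mappedAreasHa, totalN,
                                     minPerStratum = 50L, seed = NULL) {
  a <- mappedAreasHa[mappedAreasHa > 0]
  k <- length(a)
  if (k == 0L) stop("no mapped stratum with positive area")
  if (totalN < k * minPerStratum)
    stop("infeasible allocation: totalN = ", totalN, " < ",
         k, " strata x floor ", minPerStratum)
  pinned <- rep(FALSE, k)
  repeat {
    free <- !pinned
    nFree <- totalN - sum(pinned) * minPerStratum
    share <- a[free] / sum(a[free]) * nFree
    newlyPinned <- free & replace(rep(FALSE, k), which(free)[share < minPerStratum], TRUE)
    if (!any(newlyPinned & !pinned)) break
    pinned <- pinned | newlyPinned
  }
  counts <- integer(k)
  counts[pinned] <- minPerStratum
  if (any(!pinned))
    counts[!pinned] <- largestRemainder(a[!pinned],
                                        totalN - sum(counts[pinned]))
  out <- integer(length(mappedAreasHa))
  names(out) <- names(mappedAreasHa)
  out[mappedAreasHa > 0] <- counts
  out
}

#' Draw stratified random validation points on a class map
#'
#' Uniform random sampling without replacement within each map stratum;
#' deterministic under the seed.
#'
#' @param map a \linkS4class{ClassMap}.
#' @param allocation named integer vector of per-class counts (names = class
#'   codes).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{row}, \code{col}, \code{mapClass}.
#' @export
drawValidationPoints <- function(map, allocation, seed = 1L) {
  stopifnot(is(map, "ClassMap"))
  set.seed(as.integer(seed))
  g <- map@grid
  out <- list()
  for (nm in names(allocation)) {
    nAlloc <- allocation[[nm]]
    if (nAlloc == 0L) next
    cl <- as.integer(nm)
    idx <- which(g == cl)
    if (length(idx) < nAlloc)
      stop("stratum ", lucipName(cl), " has ", length(idx),
           " pixels but ", nAlloc, " points were allocated")
    pick <- idx[sample.int(length(idx), nAlloc)]
    out[[nm]] <- data.frame(
      row = (pick - 1L) %% nrow(g) + 1L,
      col = (pick - 1L) %/% nrow(g) + 1L,
      mapClass = cl
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate reference labelling of validation points
#'
#' Stands in for manual photo-interpretation of the validation points:
#' labels each point with the truth map's class at its location, optionally
#' corrupting a seeded fraction of labels to a uniformly drawn different
#' class (emulating interpreter error).
#'
#' @param points data.frame from \code{\link{drawValidationPoints}}.
#' @param truth a \linkS4class{ClassMap}.
#' @param errorRate probability a label is replaced by a wrong class.
#' @param seed integer RNG seed.
#' @return the data.frame with a \code{refClass} column appended.
#' @export
simulateReferenceLabels <- function(points, truth, errorRate = 0, seed = 1L) {
  stopifnot(is(truth, "ClassMap"))
  ref <- truth@grid[cbind(points$row, points$col)]
  if (errorRate > 0) {
    set.seed(as.integer(seed))
    flip <- stats::runif(length(ref)) < errorRate
    if (any(flip)) {
      ref[flip] <- vapply(ref[flip], function(cl)
        sample(setdiff(1:7, cl), 1L), integer(1))
    }
  }
  points$refClass <- ref
  points
}

#' Build a confusion matrix from paired labels
#'
#' Cross-tabulates map labels (rows, the sampling strata) against reference
#' labels (columns) over the seven LUCIP classes and attaches the mapped
#' per-stratum areas needed by the area-based estimators.
#'
#' @param mapLabels,referenceLabels equal-length vectors of class codes.
#' @param mappedAreasHa named numeric vector of mapped areas (ha), names =
#'   class codes; must cover every sampled stratum.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
buildConfusionMatrix <- function(mapLabels, referenceLabels, mappedAreasHa) {
  if (length(mapLabels) != length(referenceLabels))
    stop("label vectors must have equal length")
  if (length(mapLabels) == 0L) stop("empty label vectors")
  codes <- 1:7
  if (!all(mapLabels %in% codes) || !all(referenceLabels %in% codes))
    stop("unknown class code in labels")
  cm <- table(factor(mapLabels, levels = codes),
              factor(referenceLabels, levels = codes))
  counts <- matrix(as.integer(cm), 7L, 7L,
                   dimnames = list(as.character(codes), as.character(codes)))
  a <- stats::setNames(numeric(7L), as.character(codes))
  a[names(mappedAreasHa)] <- mappedAreasHa
  new("ConfusionMatrix", counts = counts, mappedAreasHa = a)
}

#' Assemble a ConfusionMatrix from a printed counts table
#'
#' Convenience constructor for ingesting an already tabulated cross-matrix
#' (e.g. a published accuracy table) together with the mapped stratum areas.
#'
#' @param counts square integer matrix, rows = map class; row/column names
#'   are class codes (taken from \code{rownames}, or assigned 1..k).
#' @param mappedAreasHa numeric vector of mapped areas, one per row.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrixFromCounts <- function(counts, mappedAreasHa) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- colnames(counts) <- as.character(seq_len(nrow(counts)))
  colnames(counts) <- rownames(counts)
  storage.mode(counts) <- "integer"
  names(mappedAreasHa) <- rownames(counts)
  new("ConfusionMatrix", counts = counts, mappedAreasHa = mappedAreasHa)
}

#' Accuracy statistics from a confusion matrix
#'
#' Overall accuracy OA = 100 * sum(n_ii) / n; user's accuracy UA_i = 100 *
#' n_ii / n_i. per map class (commission view); producer's accuracy PA_j =
#' 100 * n_jj / n_.j per reference class (omission view). Values are carried
#' at full precision; classes with a zero row (or column) total have
#' undefined UA (or PA), reported as NA rather than 0. Use
#' \code{\link{formatAccuracy}} for the printed-style integer display.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return list with elements \code{oa} (scalar percent), \code{ua},
#'   \code{pa} (named vectors, percent), \code{n} (total points) and
#'   \code{correct} (diagonal sum).
#' @export
accuracyReport <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  n <- sum(m)
  if (n == 0L) stop("confusion matrix is empty")
  d <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  ua <- ifelse(rs > 0, 100 * d / rs, NA_real_)
  pa <- ifelse(cs > 0, 100 * d / cs, NA_real_)
  list(oa = 100 * sum(d) / n,
       ua = stats::setNames(ua, rownames(m)),
       pa = stats::setNames(pa, colnames(m)),
       n = n, correct = sum(d))
}

#' @rdname accuracyReport
#' @param report a list from \code{accuracyReport}.
#' @return \code{formatAccuracy}: data.frame of truncated integer percents
#'   (the convention of printed accuracy tables; stored values keep full
#'   precision).
#' @export
formatAccuracy <- function(report) {
  data.frame(class = names(report$ua),
             UA = truncPercent(report$ua),
             PA = truncPercent(report$pa),
             row.names = NULL)
}

#' Area-based error matrix
#'
#' Re-expresses the confusion-matrix cells as estimated area proportions,
#' p_ij = W_i * n_ij / n_i., where W_i = A_i / sum(A) is the mapped-area
#' weight of stratum i. Cells sum to 1 over the sampled strata.
#'
#' @param cm a \linkS4class{ConfusionMatrix} with mapped areas for every
#'   sampled stratum.
#' @return numeric matrix of proportions, same dimnames as the counts.
#' @export
areaErrorMatrix <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  rs <- rowSums(m)
  a <- cm@mappedAreasHa
  if (any(rs > 0 & a <= 0))
    stop("missing mapped area for a sampled stratum")
  W <- a / sum(a)
  p <- m * 0
  sampled <- rs > 0
  p[sampled, ] <- (W[sampled] / rs[sampled]) * m[sampled, , drop = FALSE]
  p
}

#' Unbiased class-area estimates from a stratified validation sample
#'
#' Good-practice stratified estimators: the reference-class proportion is
#' p_.j = sum_i W_i n_ij / n_i., the unbiased area A_j = p_.j * A_total, and
#' the standard error
#' SE(p_.j) = sqrt( sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1) ),
#' with SE(A_j) = A_total * SE(p_.j) and a 95% confidence interval
#' A_j +/- 1.96 SE(A_j). Strata sampled with fewer than 2 points make the
#' SE undefined and raise an error.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return data.frame with one row per class: \code{class}, \code{propRef},
#'   \code{areaHa}, \code{seHa}, \code{ciLowHa}, \code{ciHighHa}, plus
#'   attributes \code{W} (stratum weights) and \code{totalAreaHa}.
#' @export
unbiasedAreaEstimates <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  rs <- rowSums(m)
  a <- cm@mappedAreasHa
  if (any(rs == 1L))
    stop("standard error undefined: stratum sampled with a single point: ",
         paste(rownames(m)[rs == 1L], collapse = ", "))
  if (any(rs == 0L & a > 0))
    stop("mapped stratum with positive area but no validation points: ",
         paste(rownames(m)[rs == 0L & a > 0], collapse = ", "))
  Atot <- sum(a)
  W <- a / Atot
  sampled <- rs > 0
  prop <- m[sampled, , drop = FALSE] / rs[sampled]
  pHat <- colSums(W[sampled] * prop)
  varP <- colSums(W[sampled]^2 * prop * (1 - prop) / (rs[sampled] - 1))
  se <- sqrt(varP)
  areaHa <- pHat * Atot
  seHa <- se * Atot
  out <- data.frame(class = colnames(m),
                    propRef = as.numeric(pHat),
                    areaHa = as.numeric(areaHa),
                    seHa = as.numeric(seHa),
                    ciLowHa = as.numeric(areaHa - 1.96 * seHa),
                    ciHighHa = as.numeric(areaHa + 1.96 * seHa),
                    row.names = NULL)
  attr(out, "W") <- W
  attr(out, "totalAreaHa") <- Atot
  out
}

#' Area-weighted overall accuracy
#'
#' Overall accuracy computed from the area-based error matrix, 100 *
#' sum_j p_jj (percent of area correctly mapped). This weights strata by
#' mapped area and in general differs from the count-based OA of
#' \code{\link{accuracyReport}}; both are reported, never conflated.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return scalar percent.
#' @export
areaWeightedOA <- function(cm) {
  100 * sum(diag(areaErrorMatrix(cm)))
}

#' Tabulate class areas by management region
#'
#' For each named region polygon, counts the map pixels whose centre falls
#' inside the region and reports per-class areas (pixel count x pixel area);
#' region totals equal the region's pixel area. An empty region yields a
#' zero row with a warning.
#'
#' @param map a \linkS4class{ClassMap}.
#' @param regions named list of closed-ring coordinate matrices (pixel
#'   units, as in \linkS4class{TrainingPolygons}).
#' @return data.frame: one row per region, columns = class names plus
#'   \code{total} (ha).
#' @export
zonalTabulate <- function(map, regions) {
  stopifnot(is(map, "ClassMap"))
  g <- map@grid
  h <- nrow(g); w <- ncol(g)
  ctr <- pixelCentres(h, w)
  classes <- lucipClasses()
  rows <- lapply(names(regions), function(nm) {
    inside <- pointsInRing(ctr$x, ctr$y, regions[[nm]])
    if (!any(inside)) warning("region '", nm, "' contains no pixel centre")
    cl <- as.vector(g)[inside]
    cnt <- tabulate(factor(cl[cl != 0L], levels = classes$code), nbins = 7L)
    areas <- cnt * map@pixelSizeHa
    stats::setNames(c(areas, sum(areas)), c(classes$name, "total"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(region = names(regions), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
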