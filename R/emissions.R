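#' Load and validate a tiered emission-factor table
#'
#' Reads an emission-factor (EF) table with columns \code{class},
#' \code{tier} (T1 = IPCC default, T2 = country-specific), \code{ef_mean},
#' \code{ef_low}, \code{ef_high} (t CO2-C ha^-1 y^-1; low/high are the 95%
#' CI bounds), optional \code{n_sites}, \code{source} and
#' \code{published_emission_t}. Validates class names, tier labels and CI
#' ordering (\code{ef_low <= ef_mean <= ef_high}).
#'
#' The packaged default (used when \code{path} is NULL) covers the four
#' dominant classes of drained raised bogs -- cutover, cutaway, forestry and
#' grassland -- with IPCC Wetlands Supplement Tier-1 factors and
#' literature-based Irish Tier-2 factors; remnant peatland, water and
#' built-up have no published EF and are deliberately absent.
#'
#' @param path CSV file path, or NULL for the packaged default.
#' @return data.frame of validated EF records.
#' @export
loadEmissionFactors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "emission_factors.csv",
                        package = "peatluc", mustWork = TRUE)
  ef <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("class", "tier", "ef_mean", "ef_low", "ef_high")
  if (!all(needed %in% names(ef)))
    stop("EF table must have columns: ", paste(needed, collapse = ", "))
  bad <- !(ef$class %in% lucipClasses()$name)
  if (any(bad)) stop("unknown class in EF table: ",
                     paste(unique(ef$class[bad]), collapse = ", "))
  if (!all(ef$tier %in% c("T1", "T2")))
    stop("tier must be T1 or T2")
  if (any(ef$ef_low > ef$ef_mean | ef$ef_mean > ef$ef_high))
    stop("malformed EF confidence interval: ef_low <= ef_mean <= ef_high required")
  if (anyDuplicated(ef[c("class", "tier")]))
    stop("duplicate (class, tier) EF record")
  ef
}

#' Packaged class areas of the mapped raised-bog land uses
#'
#' The per-class unbiased land-use areas (ha) that the packaged EF table's
#' published emission values refer to, shipped as fixed inputs for the
#' emission-accounting examples.
#'
#' @return named numeric vector of areas in hectares (names = class names).
#' @export
defaultClassAreas <- function() {
  path <- system.file("extdata", "class_areas.csv", package = "peatluc",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$area_ha, tab$class)
}

#' Compute per-class, per-tier CO2-C emissions
#'
#' Applies emission = area (ha) x EF (t CO2-C ha^-1 y^-1) per class and tier,
#' with the uncertainty range (area x ef_low, area x ef_high) from the EF
#' confidence bounds. Values are carried at full precision; see
#' \code{\link{formatEmissionTable}} for display rounding. Classes with
#' positive area but no EF record are listed as excluded, never as zeros.
#' If the EF table carries \code{published_emission_t} values, each computed
#' emission is checked against them and discrepancies beyond 1 t are
#' flagged in the report's \code{notes} (including the case where the
#' published value instead matches another class's EF, indicating swapped
#' labels in the source table).
#'
#' @param areasHa named numeric vector of class areas in hectares (names =
#'   class names), all >= 0.
#' @param efs EF table from \code{\link{loadEmissionFactors}}.
#' @return list of class \code{"EmissionReport"}: \code{perClass}
#'   (data.frame class/tier/area_ha/ef_mean/emission_t/range_low_t/
#'   range_high_t), \code{totals} (per-tier sums in t and Mt with ranges),
#'   \code{excluded} (character), \code{notes} (character).
#' @export
computeEmissions <- function(areasHa, efs = loadEmissionFactors()) {
  if (any(areasHa < 0)) stop("negative area")
  if (is.null(names(areasHa)) || !all(names(areasHa) %in% lucipClasses()$name))
    stop("areasHa must be named with valid class names")
  withEF <- unique(efs$class)
  excluded <- names(areasHa)[areasHa > 0 & !(names(areasHa) %in% withEF)]

  rows <- efs[efs$class %in% names(areasHa), , drop = FALSE]
  area <- areasHa[rows$class]
  perClass <- data.frame(
    class = rows$class,
    tier = rows$tier,
    area_ha = as.numeric(area),
    ef_mean = rows$ef_mean,
    emission_t = as.numeric(area * rows$ef_mean),
    range_low_t = as.numeric(area * rows$ef_low),
    range_high_t = as.numeric(area * rows$ef_high),
    stringsAsFactors = FALSE
  )
  perClass <- perClass[order(perClass$tier, lucipCode(perClass$class)), ]
  rownames(perClass) <- NULL

  notes <- character(0)
  if ("published_emission_t" %in% names(rows)) {
    for (i in seq_len(nrow(perClass))) {
      r <- perClass[i, ]
      pub <- rows$published_emission_t[rows$class == r$class &
                                         rows$tier == r$tier]
      if (length(pub) != 1L || is.na(pub)) next
      if (abs(r$emission_t - pub) > 1) {
        # does the published value match a different class's EF of this tier?
        others <- rows[rows$tier == r$tier & rows$class != r$class, ]
        alt <- others$class[abs(r$area_ha * others$ef_mean - pub) <= 1]
        msg <- sprintf(
          "%s %s: computed %.0f t differs from published %.0f t",
          r$class, r$tier, r$emission_t, pub)
        if (length(alt))
          msg <- paste0(msg, sprintf(
            " (published value equals area x the %s EF: labels appear swapped)",
            paste(alt, collapse = "/")))
        notes <- c(notes, msg)
      }
    }
  }

  agg <- function(tier) {
    p <- perClass[perClass$tier == tier, , drop = FALSE]
    data.frame(tier = tier,
               total_t = sum(p$emission_t),
               total_Mt = sum(p$emission_t) / 1e6,
               range_low_Mt = sum(p$range_low_t) / 1e6,
               range_high_Mt = sum(p$range_high_t) / 1e6,
               range_type = "naive classwise EF-bound sum",
               stringsAsFactors = FALSE)
  }
  totals <- do.call(rbind, lapply(unique(perClass$tier), agg))

  structure(list(perClass = perClass, totals = totals,
                 excluded = excluded, notes = notes),
            class = "EmissionReport")
}

#' Total emissions for one tier
#'
#' Sum of the included classes' emissions, in Mt CO2-C y^-1, with the naive
#' uncertainty range obtained by summing the classwise EF-bound products
#' (a perfect-dependence assumption, labelled as such in the report).
#'
#' @param report an \code{EmissionReport} from \code{\link{computeEmissions}}.
#' @param tier \code{"T1"} or \code{"T2"}.
#' @return named numeric vector \code{c(total_Mt, range_low_Mt,
#'   range_high_Mt)}.
#' @export
totalEmissions <- function(report, tier) {
  t <- report$totals[report$totals$tier == tier, , drop = FALSE]
  if (nrow(t) == 0L) stop("no emissions computed for tier ", tier)
  c(total_Mt = t$total_Mt, range_low_Mt = t$range_low_Mt,
    range_high_Mt = t$range_high_Mt)
}

#' Display-rounded emission table
#'
#' Per-class emissions rounded to the nearest integer tonne and tier totals
#' to 2 decimal Mt, the conventional presentation; the underlying report
#' keeps full precision.
#'
#' @param report an \code{EmissionReport}.
#' @return list with \code{perClass} (integer-tonne data.frame) and
#'   \code{totals} (2-dp Mt data.frame).
#' @export
formatEmissionTable <- function(report) {
  p <- report$perClass
  p$emission_t <- round(p$emission_t)
  p$range_low_t <- round(p$range_low_t)
  p$range_high_t <- round(p$range_high_t)
  t <- report$totals
  t$total_Mt <- round(t$total_Mt, 2)
  t$range_low_Mt <- round(t$range_low_Mt, 2)
  t$range_high_Mt <- round(t$range_high_Mt, 2)
  list(perClass = p, totals = t[, c("tier", "total_Mt", "range_low_Mt",
                                    "range_high_Mt", "range_type")])
}

#' @export
print.EmissionReport <- function(x, ...) {
  f <- formatEmissionTable(x)
  cat("CO2-C emission report (t CO2-C y^-1; totals in Mt CO2-C y^-1)\n")
  print(f$perClass, row.names = FALSE)
  print(f$totals, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (no emission factor):",
        paste(x$excluded, collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
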