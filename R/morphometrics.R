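# Deformation-index morphometrics, nuclear morphometrics, tumorsphere
# growth quantification.

#' Deformation index
#'
#' `DI = Dx / D0`, the ratio of a cell's major axis at a device location to
#' its undeformed major axis.
#'
#' @param dx major axis at the measured location (µm).
#' @param d0 undeformed (baseline) major axis (µm), > 0.
#' @return The dimensionless deformation index (vectorized).
#' @examples
#' computeDI(45, 15)  # 3
#' @export
computeDI <- function(dx, d0) {
  stopIfNot(all(d0 > 0), "D0 must be > 0")
  dx / d0
}

#' Assign a device region from a flow-axis position
#'
#' Returns the region whose flow-axis interval contains the centroid;
#' points on an interval boundary belong to the upstream region. Positions
#' outside all intervals return `"UNASSIGNED"`.
#'
#' @param x flow-axis centroid position(s) in µm.
#' @param geometry a [DeviceGeometry-class].
#' @return Character vector of region labels.
#' @export
assignRegion <- function(x, geometry) {
  stopIfNot(is(geometry, "DeviceGeometry"), "geometry must be a DeviceGeometry")
  rt <- regionIntervals(geometry)
  vapply(x, function(xi) {
    if (!is.finite(xi)) return("UNASSIGNED")
    # upstream assignment: interval (xmin, xmax], except the first region
    # also owns its left edge
    hit <- which((xi > rt$xmin & xi <= rt$xmax) |
                 (seq_len(nrow(rt)) == 1L & xi == rt$xmin))
    if (length(hit)) rt$region[hit[1L]] else "UNASSIGNED"
  }, character(1))
}

#' Percent median deformation of a region relative to baseline
#'
#' `% value = 100 * median(region DIs) / median(baseline DIs)` and
#' `% increase = % value - 100`. Medians of even-length samples are the
#' mean of the two central order statistics. A warning is issued when
#' either sample has fewer than `minN` cells (headline summaries use at
#' least 20 cells per location).
#'
#' @param regionDI deformation indices at the location of interest.
#' @param baselineDI deformation indices before deformation.
#' @param minN sample-size warning threshold.
#' @return A list with `percent`, `increase`, `nRegion`, `nBaseline`.
#' @examples
#' percentMedianDeformation(c(1, 2, 4), c(1, 1, 1))  # 200, increase 100
#' @export
percentMedianDeformation <- function(regionDI, baselineDI, minN = 20) {
  stopIfNot(length(regionDI) > 0 && length(baselineDI) > 0,
            "both DI lists must be non-empty")
  if (length(regionDI) < minN || length(baselineDI) < minN)
    warning(sprintf("fewer than %d cells in a group; summary may be unstable",
                    minN))
  mb <- median(baselineDI)
  if (mb == 0) stop("baseline median DI is zero")
  pct <- 100 * median(regionDI) / mb
  list(percent = pct, increase = pct - 100,
       nRegion = length(regionDI), nBaseline = length(baselineDI))
}

#' Nuclear morphometrics between two groups
#'
#' Mean nuclear area and mean intensity per group, with percent change
#' `100 * (mean_treated - mean_control) / mean_control`.
#'
#' @param control,treated data.frames (or lists) with numeric elements
#'   `area` and `intensity` (per-nucleus values).
#' @return A data.frame with one row per feature: group means and
#'   `pct_change`.
#' @export
nuclearMorphometrics <- function(control, treated) {
  stopIfNot(length(control$area) > 0 && length(treated$area) > 0,
            "both groups must be non-empty")
  feats <- c("area", "intensity")
  do.call(rbind, lapply(feats, function(f) {
    mc <- mean(control[[f]]); mt <- mean(treated[[f]])
    data.frame(feature = f, mean_control = mc, mean_treated = mt,
               pct_change = 100 * (mt - mc) / mc)
  }))
}

#' Fit a linear tumorsphere growth rate
#'
#' Growth rate is the ordinary least-squares slope of mean sphere area
#' versus day.
#'
#' @param track data.frame with columns `day` and `area` (mean area per
#'   day, µm²); at least 3 timepoints.
#' @return A list with `rate` (µm²/day), `intercept`, and the `fit` object.
#' @seealso [growthRateRatio()]
#' @export
fitGrowth <- function(track) {
  stopIfNot(is.data.frame(track) && all(c("day", "area") %in% names(track)),
            "track needs columns day and area")
  stopIfNot(length(unique(track$day)) >= 3, "need at least 3 timepoints")
  fit <- lm(area ~ day, data = track)
  list(rate = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit = fit)
}

#' Ratio of growth rates between two conditions
#'
#' @param fitA,fitB outputs of [fitGrowth()] (numerator / denominator).
#' @return A list with `ratio` and a `flag` set when the denominator rate
#'   is zero (ratio undefined, returned as `NA`).
#' @export
growthRateRatio <- function(fitA, fitB) {
  tol <- 1e-9 * max(1, abs(fitA$rate))
  if (abs(fitB$rate) < tol)
    return(list(ratio = NA_real_, flag = "zero denominator growth rate"))
  list(ratio = fitA$rate / fitB$rate, flag = NA_character_)
}

# ---------------------------------------------------------------------------
# End-to-end transit morphometrics: segment rendered region frames, link
# cells to the baseline frame, compute DI per cell and summarize.
# ---------------------------------------------------------------------------

# segment one transit frame and return per-cell centroid/major axis
measureTransitFrame <- function(stack) {
  m <- getFrame(stack)
  mask <- segmentNuclei(m, pixelSize = pixelSize(stack), minArea = 10,
                        splitTouching = FALSE)
  extractFeatures(mask, channels = list(brightfield = m),
                  origin = stackOrigin(stack))
}

#' Deformation-index analysis of a transit sequence
#'
#' Segments every region frame, measures moment-ellipse major axes, links
#' each cell to its BASELINE counterpart by nearest lane (y centroid), and
#' computes per-cell deformation indices with the per-cell baseline D0.
#' When linking is disabled the cohort baseline median D0 is used instead
#' (flagged in the output).
#'
#' @param stacks named list of per-region [ImageStack-class] frames, as
#'   produced by [generateTransitSequence()]; must include a `BASELINE`
#'   entry.
#' @param geometry the [DeviceGeometry-class] used for region assignment.
#' @param linkCells link cells across frames by nearest y centroid
#'   (default); otherwise use the cohort baseline median D0.
#' @return A data.frame of shape records: `cell`, `region`, `major_um`,
#'   `d0_um`, `di`, `x_um`, `y_um`, `d0_source`.
#' @seealso [deformationSummary()]
#' @export
transitMorphometrics <- function(stacks, geometry, linkCells = TRUE) {
  stopIfNot("BASELINE" %in% names(stacks), "stacks must include BASELINE")
  base <- measureTransitFrame(stacks[["BASELINE"]])
  stopIfNot(nrow(base) > 0, "no cells detected in the BASELINE frame")
  d0med <- median(base$major_um)
  out <- vector("list", length(stacks))
  for (k in seq_along(stacks)) {
    reg <- names(stacks)[k]
    f <- measureTransitFrame(stacks[[k]])
    if (nrow(f) == 0) next
    if (linkCells) {
      idx <- vapply(f$centroid_y_um, function(y)
        which.min(abs(base$centroid_y_um - y)), integer(1))
      d0 <- base$major_um[idx]
      cellId <- idx
      src <- "per-cell baseline"
    } else {
      d0 <- rep(d0med, nrow(f))
      cellId <- f$label
      src <- "cohort baseline median"
    }
    out[[k]] <- data.frame(cell = cellId, region = reg,
                           major_um = f$major_um, d0_um = d0,
                           di = computeDI(f$major_um, d0),
                           x_um = f$centroid_x_um, y_um = f$centroid_y_um,
                           d0_source = src, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-region deformation summary
#'
#' Median DI, percent median deformation and percent increase per region,
#' relative to the BASELINE records.
#'
#' @param shapes shape records from [transitMorphometrics()] (or any
#'   data.frame with `region` and `di`).
#' @param minN sample-size warning threshold (headline summaries use
#'   >= 20 cells).
#' @return A data.frame with one row per region: `region`, `n`,
#'   `median_di`, `pct_median_deformation`, `pct_increase`.
#' @export
deformationSummary <- function(shapes, minN = 20) {
  stopIfNot(all(c("region", "di") %in% names(shapes)),
            "shapes needs columns region and di")
  baseDI <- shapes$di[shapes$region == "BASELINE"]
  stopIfNot(length(baseDI) > 0, "no BASELINE records")
  regions <- unique(shapes$region)
  do.call(rbind, lapply(regions, function(r) {
    di <- shapes$di[shapes$region == r]
    p <- percentMedianDeformation(di, baseDI, minN = minN)
    data.frame(region = r, n = p$nRegion, median_di = median(di),
               pct_median_deformation = p$percent,
               pct_increase = p$increase, stringsAsFactors = FALSE)
  }))
}

#' Quantify tumorsphere areas over a time series
#'
#' Segments the largest sphere in each frame and returns its area per day.
#'
#' @param stack brightfield [ImageStack-class], one frame per day; frame
#'   days are read from `metadata$days` when present, else `0, 1, ...`.
#' @param polarity passed to [segmentSpheres()].
#' @return A data.frame `day`, `area` (µm²) suitable for [fitGrowth()].
#' @export
sphereTrack <- function(stack, polarity = "dark") {
  d <- imgData(stack)
  nT <- dim(d)[4L]
  days <- stack@metadata$days
  if (is.null(days)) days <- seq_len(nT) - 1
  areas <- vapply(seq_len(nT), function(t) {
    res <- segmentSpheres(d[, , 1L, t], pixelSize = pixelSize(stack),
                          polarity = polarity)
    if (nrow(res$areas) == 0) NA_real_ else max(res$areas$area_um2)
  }, numeric(1))
  data.frame(day = days, area = areas)
}
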