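# Synthetic immunofluorescence plates: non-overlapping cells (nucleus disk
# inside a larger cell body) imaged in DAPI, actin and marker channels, with
# multiplicative flatfield + additive darkfield illumination bias and camera
# noise. Ground truth carries the per-cell compartment means actually used
# for rendering.

#' Specification of a synthetic IF plate
#'
#' @param nWells number of wells (>= 1).
#' @param cellsPerWell cells rendered per well.
#' @param conditions condition label per well, recycled (`control`/`squeeze`).
#' @param timepoint timepoint label stored in the ground truth.
#' @param markers marker channel names.
#' @param nuclearMean named per-marker nuclear mean intensity (control).
#' @param cytoMean named per-marker cytoplasmic mean intensity (control).
#' @param effectSize named per-marker multiplicative effect applied to both
#'   compartments in treated (non-control) wells; must be >= 0.
#' @param dapiMean,actinMean DAPI and actin foreground intensities.
#' @param cellCV lognormal cell-to-cell coefficient of variation of marker
#'   expression.
#' @param nucleusRadius,cellRadius compartment radii in µm.
#' @param imageSize well image side in pixels.
#' @param pixelSize µm per pixel.
#' @param vignettingStrength radial flatfield drop at the image corner
#'   (0 = uniform illumination; 0.5 = corner at half the centre intensity).
#' @param darkfieldLevel constant additive darkfield intensity.
#' @param readNoiseSd,photonScale camera noise model (see
#'   [squeezeModelParams()]).
#' @param seed integer RNG seed.
#' @return A validated `PlateSpec` list.
#' @export
plateSpec <- function(nWells = 8,
                      cellsPerWell = 40,
                      conditions = c("control", "squeeze"),
                      timepoint = "4h",
                      markers = c("CD44", "ABCB5"),
                      nuclearMean = NULL,
                      cytoMean = NULL,
                      effectSize = NULL,
                      dapiMean = 500,
                      actinMean = 250,
                      cellCV = 0.25,
                      nucleusRadius = 5,
                      cellRadius = 9,
                      imageSize = 256,
                      pixelSize = 1,
                      vignettingStrength = 0.3,
                      darkfieldLevel = 5,
                      readNoiseSd = 3,
                      photonScale = 0.5,
                      seed = 1L) {
  stopIfNot(nWells >= 1, "need at least one well")
  if (is.null(nuclearMean)) nuclearMean <- setNames(rep(120, length(markers)), markers)
  if (is.null(cytoMean))    cytoMean    <- setNames(rep(60,  length(markers)), markers)
  if (is.null(effectSize))  effectSize  <- setNames(rep(1,   length(markers)), markers)
  stopIfNot(all(markers %in% names(nuclearMean)) &&
            all(markers %in% names(cytoMean)) &&
            all(markers %in% names(effectSize)),
            "nuclearMean, cytoMean and effectSize must name every marker")
  if (any(effectSize < 0)) stop("invalid plate spec: effect size must be >= 0")
  stopIfNot(all(nuclearMean >= 0) && all(cytoMean >= 0),
            "invalid plate spec: intensities must be >= 0")
  stopIfNot(nucleusRadius < cellRadius, "nucleus must fit inside the cell body")
  structure(list(nWells = nWells, cellsPerWell = cellsPerWell,
                 conditions = rep(conditions, length.out = nWells),
                 timepoint = timepoint, markers = markers,
                 nuclearMean = nuclearMean[markers],
                 cytoMean = cytoMean[markers],
                 effectSize = effectSize[markers],
                 dapiMean = dapiMean, actinMean = actinMean, cellCV = cellCV,
                 nucleusRadius = nucleusRadius, cellRadius = cellRadius,
                 imageSize = as.integer(imageSize), pixelSize = pixelSize,
                 vignettingStrength = vignettingStrength,
                 darkfieldLevel = darkfieldLevel,
                 readNoiseSd = readNoiseSd, photonScale = photonScale,
                 seed = as.integer(seed)),
            class = "PlateSpec")
}

# radial quadratic flatfield, normalized to mean 1 over the field
makeFlatfield <- function(n, strength) {
  if (strength <= 0) return(matrix(1, n, n))
  ctr <- (n - 1) / 2
  r2 <- outer(((0:(n - 1)) - ctr)^2, ((0:(n - 1)) - ctr)^2, "+")
  f <- 1 - strength * r2 / max(r2)
  f / mean(f)
}

# uniform rejection-sampled cell centres guaranteeing non-overlap (pixels,
# 0-based); uniform placement keeps the ensemble coverage probability
# spatially flat, which the illumination estimator relies on
placeCells <- function(nCells, imageSize, cellRadiusPx) {
  marg <- cellRadiusPx + 2
  minDist2 <- (2 * cellRadiusPx + 2)^2
  ys <- numeric(nCells); xs <- numeric(nCells)
  placed <- 0L
  for (att in seq_len(500L * nCells)) {
    y <- runif(1, marg, imageSize - 1 - marg)
    x <- runif(1, marg, imageSize - 1 - marg)
    if (placed == 0L ||
        all((ys[seq_len(placed)] - y)^2 + (xs[seq_len(placed)] - x)^2 >=
            minDist2)) {
      placed <- placed + 1L
      ys[placed] <- y; xs[placed] <- x
      if (placed == nCells) break
    }
  }
  stopIfNot(placed == nCells,
            "cellsPerWell too large for imageSize at this cell radius")
  data.frame(y = ys, x = xs)
}

#' Generate a synthetic immunofluorescence plate
#'
#' Each well image carries a DAPI channel (nuclei), an actin channel (cell
#' bodies) and one channel per marker. The observed image is
#' `truth * flatfield + darkfield + noise`. Cells never overlap, so the
#' segmentation ground truth is unambiguous.
#'
#' @param spec a [plateSpec()].
#' @return A list with `wells` (list of multi-channel [ImageStack-class], one
#'   per well), `truth` (ground-truth feature table: one row per cell with
#'   realized compartment means per marker), `illumination` (the true
#'   [IlluminationModel-class]) and `spec`.
#' @examples
#' plate <- generateIFPlate(plateSpec(nWells = 2, cellsPerWell = 5))
#' nrow(plate$truth)  # 10
#' @export
generateIFPlate <- function(spec) {
  stopIfNot(inherits(spec, "PlateSpec"), "spec must come from plateSpec()")
  ps <- spec$pixelSize
  n <- spec$imageSize
  rN <- spec$nucleusRadius / ps
  rC <- spec$cellRadius / ps
  channels <- c("DAPI", "ACTIN", spec$markers)
  ff <- makeFlatfield(n, spec$vignettingStrength)
  df <- matrix(spec$darkfieldLevel, n, n)
  illum <- illuminationModel(
    flatfield = setNames(rep(list(ff), length(channels)), channels),
    darkfield = setNames(rep(list(df), length(channels)), channels),
    metadata = list(source = "generator truth"))

  withSeed(spec$seed, {
    wells <- vector("list", spec$nWells)
    truthRows <- vector("list", spec$nWells)
    cellId <- 0L
    for (w in seq_len(spec$nWells)) {
      cond <- spec$conditions[w]
      eff <- if (cond == "control") rep(1, length(spec$markers))
             else as.numeric(spec$effectSize)
      pos <- placeCells(spec$cellsPerWell, n, rC)
      nm <- spec$cellsPerWell
      dapiAmp <- spec$dapiMean * exp(rnorm(nm, 0, spec$cellCV))
      markerFac <- matrix(exp(rnorm(nm * length(spec$markers), 0, spec$cellCV)),
                          nm, length(spec$markers))
      truthImgs <- lapply(channels, function(ch) matrix(0, n, n))
      names(truthImgs) <- channels
      rows <- data.frame(cell = cellId + seq_len(nm), well = w,
                         condition = cond, timepoint = spec$timepoint,
                         y_px = pos$y, x_px = pos$x,
                         stringsAsFactors = FALSE)
      for (i in seq_len(nm)) {
        truthImgs$DAPI <- fillEllipse(truthImgs$DAPI, pos$y[i], pos$x[i],
                                      rN, rN, dapiAmp[i])
        truthImgs$ACTIN <- fillEllipse(truthImgs$ACTIN, pos$y[i], pos$x[i],
                                       rC, rC, spec$actinMean)
        for (j in seq_along(spec$markers)) {
          m <- spec$markers[j]
          nucV <- spec$nuclearMean[[m]] * eff[j] * markerFac[i, j]
          cytV <- spec$cytoMean[[m]] * eff[j] * markerFac[i, j]
          truthImgs[[m]] <- fillEllipse(truthImgs[[m]], pos$y[i], pos$x[i],
                                        rC, rC, cytV)
          truthImgs[[m]] <- fillEllipse(truthImgs[[m]], pos$y[i], pos$x[i],
                                        rN, rN, nucV)
          rows[[paste0("true_nuc_", m)]][i] <- nucV
          rows[[paste0("true_cyto_", m)]][i] <- cytV
        }
        rows$true_dapi[i] <- dapiAmp[i]
      }
      obs <- array(0, c(n, n, length(channels), 1L))
      for (k in seq_along(channels)) {
        o <- truthImgs[[k]] * ff + df
        obs[, , k, 1L] <- addCameraNoise(o, spec$readNoiseSd, spec$photonScale)
      }
      wells[[w]] <- imageStack(obs, pixelSize = ps, channelNames = channels,
                               metadata = list(well = w, condition = cond,
                                               seed = spec$seed))
      truthRows[[w]] <- rows
      cellId <- cellId + nm
    }
    list(wells = wells, truth = do.call(rbind, truthRows),
         illumination = illum, spec = spec)
  })
}

#' Stack one channel of a plate across wells
#'
#' Convenience for illumination estimation: returns an [ImageStack-class]
#' whose time axis runs over wells for the requested channels.
#'
#' @param plate output of [generateIFPlate()].
#' @param channels channels to keep (default all).
#' @return An [ImageStack-class] with `(y, x, channel, well)` axes.
#' @export
plateChannelStack <- function(plate, channels = NULL) {
  s1 <- plate$wells[[1]]
  if (is.null(channels)) channels <- channelNames(s1)
  ci <- match(channels, channelNames(s1))
  stopIfNot(!anyNA(ci), "unknown channel requested")
  d <- dim(imgData(s1))
  out <- array(0, c(d[1], d[2], length(ci), length(plate$wells)))
  for (w in seq_along(plate$wells))
    out[, , , w] <- imgData(plate$wells[[w]])[, , ci, 1L]
  imageStack(out, pixelSize = pixelSize(s1), channelNames = channels,
             metadata = list(source = "plateChannelStack"))
}

#' Simulate a single-cell feature table without rendering images
#'
#' Draws per-cell compartment mean intensities directly from the same
#' statistical model the plate renderer uses (lognormal cell-to-cell
#' variation around condition means, multiplied by the treated effect size,
#' plus lognormal measurement noise). Used for statistical calibration runs
#' where rendering and segmenting hundreds of plates would add nothing: the
#' measurement layer is exercised separately by the segmentation tests.
#'
#' @param nCellsPerGroup cells per condition per timepoint.
#' @param markers marker names.
#' @param effectSize named per-marker multiplicative effect in the squeeze
#'   group.
#' @param timepoints timepoint labels.
#' @param nuclearMean,cytoMean named per-marker control compartment means.
#' @param cellCV lognormal cell-to-cell coefficient of variation.
#' @param measureCV lognormal measurement noise CV.
#' @param seed integer RNG seed.
#' @return A data.frame with one row per cell: `cell`, `condition`,
#'   `timepoint`, and `mean_<marker>_nucleus` / `mean_<marker>_cytoplasm`
#'   columns.
#' @export
simulateFeatureTable <- function(nCellsPerGroup = 200,
                                 markers = c("CD44", "ABCB5"),
                                 effectSize = NULL,
                                 timepoints = "4h",
                                 nuclearMean = NULL,
                                 cytoMean = NULL,
                                 cellCV = 0.25,
                                 measureCV = 0.05,
                                 seed = 1L) {
  if (is.null(effectSize)) effectSize <- setNames(rep(1, length(markers)), markers)
  if (is.null(nuclearMean)) nuclearMean <- setNames(rep(120, length(markers)), markers)
  if (is.null(cytoMean)) cytoMean <- setNames(rep(60, length(markers)), markers)
  if (any(effectSize < 0)) stop("invalid spec: effect size must be >= 0")
  withSeed(seed, {
    grid <- expand.grid(condition = c("control", "squeeze"),
                        timepoint = timepoints, stringsAsFactors = FALSE)
    out <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      cond <- grid$condition[g]
      df <- data.frame(cell = seq_len(nCellsPerGroup),
                       condition = cond, timepoint = grid$timepoint[g],
                       stringsAsFactors = FALSE)
      for (m in markers) {
        eff <- if (cond == "control") 1 else effectSize[[m]]
        fac <- exp(rnorm(nCellsPerGroup, 0, cellCV))
        mn <- exp(rnorm(nCellsPerGroup, 0, measureCV))
        mc <- exp(rnorm(nCellsPerGroup, 0, measureCV))
        df[[paste0("mean_", m, "_nucleus")]] <- nuclearMean[[m]] * eff * fac * mn
        df[[paste0("mean_", m, "_cytoplasm")]] <- cytoMean[[m]] * eff * fac * mc
      }
      out[[g]] <- df
    }
    res <- do.call(rbind, out)
    res$cell <- seq_len(nrow(res))
    res
  })
}
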