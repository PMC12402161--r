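# Synthetic transit sequences through the constriction device.
#
# Deformation model: 2D projected-area conservation of an ellipse. In a
# constrictive channel of width w below the cell's resting diameter D0 the
# minor axis is clamped to w and the major axis becomes D0^2 / w, so the
# projected area pi*(D0/2)^2 is conserved. In the relaxation chamber that
# follows, a retention fraction rho in [0, 1] interpolates between full
# elastic recovery (rho = 0, major axis back to D0) and full retention
# (rho = 1, major axis unchanged): major = D0 * (1 + rho * (D0/w - 1)).

#' Parameters of the synthetic squeeze model
#'
#' @param baselineDiameterMean mean resting cell diameter D0 in µm.
#' @param baselineDiameterSd SD of D0 in µm.
#' @param retentionFraction retained-deformation fraction rho per channel,
#'   recycled to the number of channels; 0 = full recovery in the relaxation
#'   chamber, 1 = no recovery.
#' @param foreground rendered cell intensity (arbitrary units).
#' @param backgroundLevel additive background intensity.
#' @param readNoiseSd Gaussian read-noise SD.
#' @param photonScale Poisson-like photon noise scale (variance per unit
#'   signal).
#' @param seed integer RNG seed.
#' @return A validated parameter list of class `SqueezeModelParams`.
#' @export
squeezeModelParams <- function(baselineDiameterMean = 15,
                               baselineDiameterSd = 1,
                               retentionFraction = 0.3,
                               foreground = 1000,
                               backgroundLevel = 10,
                               readNoiseSd = 5,
                               photonScale = 0.5,
                               seed = 1L) {
  stopIfNot(baselineDiameterMean > 0 && baselineDiameterSd >= 0,
            "baseline diameters must be positive")
  stopIfNot(all(retentionFraction >= 0 & retentionFraction <= 1),
            "retentionFraction must lie in [0, 1]")
  structure(list(baselineDiameterMean = baselineDiameterMean,
                 baselineDiameterSd = baselineDiameterSd,
                 retentionFraction = retentionFraction,
                 foreground = foreground,
                 backgroundLevel = backgroundLevel,
                 readNoiseSd = readNoiseSd,
                 photonScale = photonScale,
                 seed = as.integer(seed)),
            class = "SqueezeModelParams")
}

# true axes of one cell in one region under the squeeze model
squeezeAxes <- function(d0, region, widths, rho) {
  if (region == "BASELINE") return(c(major = d0, minor = d0))
  type <- sub("_.*$", "", region)
  w <- as.numeric(sub("^.._", "", region))
  i <- match(w, widths)
  if (w >= d0) return(c(major = d0, minor = d0))
  if (type == "CC") {
    major <- d0^2 / w
  } else {
    major <- d0 * (1 + rho[i] * (d0 / w - 1))
  }
  c(major = major, minor = d0^2 / major)
}

#' Generate a synthetic constriction-transit image sequence
#'
#' Renders each cell as a filled ellipse in every device region (one frame
#' per region, cells stacked in horizontal lanes so they never overlap), plus
#' an undeformed BASELINE frame upstream of the first channel. The returned
#' ground truth records the exact axes, deformation indices and centroid
#' positions used for rendering, making the sequence a parameter-recovery
#' target for the morphometrics pipeline.
#'
#' @param geometry a [DeviceGeometry-class].
#' @param params a [squeezeModelParams()] list.
#' @param nCells number of cells (>= 0; 0 yields empty output).
#' @return A list with `stacks` (named list of single-frame [ImageStack-class]
#'   objects, one per region, origin recording the device x-offset) and
#'   `truth` (data.frame: `cell`, `region`, `d0`, `major`, `minor`, `di`,
#'   `x_um`, `y_um`).
#' @examples
#' geom <- deviceGeometry(pixelSize = 1)
#' out <- generateTransitSequence(geom, squeezeModelParams(seed = 7), 3)
#' subset(out$truth, region == "CC_5")
#' @export
generateTransitSequence <- function(geometry, params, nCells) {
  validObject(geometry)
  stopIfNot(inherits(params, "SqueezeModelParams"),
            "params must come from squeezeModelParams()")
  stopIfNot(nCells >= 0, "nCells must be >= 0")
  ps <- pixelSize(geometry)
  widths <- channelWidths(geometry)
  rho <- rep(params$retentionFraction, length.out = length(widths))
  rt <- regionIntervals(geometry)

  if (nCells == 0) {
    return(list(stacks = list(),
                truth = data.frame(cell = integer(), region = character(),
                                   d0 = numeric(), major = numeric(),
                                   minor = numeric(), di = numeric(),
                                   x_um = numeric(), y_um = numeric())))
  }

  withSeed(params$seed, {
    d0 <- rnorm(nCells, params$baselineDiameterMean, params$baselineDiameterSd)
    d0 <- pmax(d0, 4 * ps)
    dmax <- max(d0)
    # worst-case major axis over all regions sets lane height and margins
    maxMajor <- max(dmax, dmax^2 / min(widths))
    laneH <- ceiling(dmax * 1.6)                       # µm per lane
    margin <- ceiling(maxMajor / 2 + 4 * ps)           # µm beyond region
    ny <- as.integer(ceiling(nCells * laneH / ps))
    laneC <- (seq_len(nCells) - 0.5) * laneH           # lane centres, µm

    truth <- vector("list", nrow(rt))
    stacks <- vector("list", nrow(rt))
    names(stacks) <- rt$region
    for (k in seq_len(nrow(rt))) {
      reg <- rt$region[k]
      x0 <- rt$xmin[k] - margin
      nx <- as.integer(ceiling((rt$xmax[k] - rt$xmin[k] + 2 * margin) / ps))
      img <- matrix(params$backgroundLevel, ny, nx)
      ax <- numeric(nCells); ay <- numeric(nCells)
      xc <- numeric(nCells)
      for (i in seq_len(nCells)) {
        axes <- squeezeAxes(d0[i], reg, widths, rho)
        ax[i] <- axes["major"] / 2
        ay[i] <- axes["minor"] / 2
        lo <- rt$xmin[k] + 0.05 * (rt$xmax[k] - rt$xmin[k])
        hi <- rt$xmax[k] - 0.05 * (rt$xmax[k] - rt$xmin[k])
        xc[i] <- runif(1, lo, hi)
        img <- fillEllipse(img,
                           cy = laneC[i] / ps, cx = (xc[i] - x0) / ps,
                           ay = ay[i] / ps, ax = ax[i] / ps,
                           value = params$foreground + params$backgroundLevel)
      }
      img <- addCameraNoise(img, params$readNoiseSd, params$photonScale)
      stacks[[k]] <- imageStack(img, pixelSize = ps,
                                channelNames = "brightfield",
                                origin = c(0, x0),
                                metadata = list(region = reg,
                                                seed = params$seed))
      truth[[k]] <- data.frame(cell = seq_len(nCells), region = reg,
                               d0 = d0, major = 2 * ax, minor = 2 * ay,
                               di = 2 * ax / d0, x_um = xc, y_um = laneC,
                               stringsAsFactors = FALSE)
    }
    list(stacks = stacks, truth = do.call(rbind, truth))
  })
}
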