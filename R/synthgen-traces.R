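# Synthetic time series: calcium traces, dye-exchange permeability series,
# and tumorsphere brightfield growth series.

#' Generate synthetic calcium traces for cells transiting the device
#'
#' The trace sits at `baseline` before device entry and at
#' `baseline * amplitude[region]` inside each region, so the true fold
#' change per region is exactly the amplitude. Regions follow the device
#' order of `regionAmplitudes`.
#'
#' @param baseline baseline fluorescence intensity (> 0).
#' @param regionAmplitudes named per-region multiplicative influx gain
#'   (>= 0); names become the region labels on the trace.
#' @param noiseSd Gaussian noise SD added to the trace.
#' @param seed integer RNG seed.
#' @param nCells number of traces.
#' @param framesPerSegment frames per region segment (and per baseline).
#' @param frameInterval seconds between frames.
#' @return A list with `traces` (list of data.frames `time`, `intensity`,
#'   `region`, `roi`) and `truth` (data.frame `cell`, `region`,
#'   `foldChange`).
#' @export
generateCalciumSeries <- function(baseline = 100,
                                  regionAmplitudes = c(CC_30 = 1.0,
                                                       CC_20 = 1.05,
                                                       CC_10 = 1.4,
                                                       CC_5 = 1.8),
                                  noiseSd = 1,
                                  seed = 1L,
                                  nCells = 1,
                                  framesPerSegment = 10,
                                  frameInterval = 0.5) {
  stopIfNot(baseline > 0, "baseline must be > 0")
  if (any(regionAmplitudes < 0)) stop("invalid spec: amplitude must be >= 0")
  regions <- names(regionAmplitudes)
  stopIfNot(!is.null(regions), "regionAmplitudes must be named")
  withSeed(seed, {
    traces <- vector("list", nCells)
    levels <- c(BASELINE = 1, regionAmplitudes)
    segs <- rep(names(levels), each = framesPerSegment)
    vals <- baseline * rep(as.numeric(levels), each = framesPerSegment)
    for (i in seq_len(nCells)) {
      v <- vals + if (noiseSd > 0) rnorm(length(vals), 0, noiseSd) else 0
      traces[[i]] <- data.frame(
        time = (seq_along(vals) - 1) * frameInterval,
        intensity = v, region = segs, roi = i, stringsAsFactors = FALSE)
    }
    truth <- expand.grid(cell = seq_len(nCells), region = regions,
                         stringsAsFactors = FALSE)
    truth$foldChange <- as.numeric(regionAmplitudes[truth$region])
    list(traces = traces, truth = truth)
  })
}

#' Generate a synthetic tissue-compartment dye accumulation series
#'
#' Integrates first-order exchange across a barrier,
#' `dI/dt = P * (S/V) * (I_vessel - I)`, `I(0) = 0`, whose closed form is
#' `I(t) = I_vessel * (1 - exp(-P * (S/V) * t))`, sampled every
#' `frameInterval` minutes over `duration` minutes (defaults follow the
#' standard 2-min / 90-min acquisition).
#'
#' @param pTrue true permeability coefficient in cm/s (>= 0).
#' @param sOverV barrier surface-to-volume ratio in 1/cm.
#' @param iVessel vessel (donor) compartment intensity, held constant.
#' @param duration total acquisition in minutes.
#' @param frameInterval minutes between frames (> 0).
#' @param noiseSd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return A data.frame `time` (min), `intensity`, with attributes `pTrue`,
#'   `sOverV`, `iVessel`.
#' @export
generatePermeabilitySeries <- function(pTrue, sOverV = 2, iVessel = 1000,
                                       duration = 90, frameInterval = 2,
                                       noiseSd = 0, seed = 1L) {
  stopIfNot(pTrue >= 0, "pTrue must be >= 0")
  stopIfNot(frameInterval > 0, "frameInterval must be > 0")
  if (duration < 0) stop("invalid spec: negative duration")
  k <- pTrue * sOverV                      # 1/s
  tmin <- seq(0, duration, by = frameInterval)
  ideal <- iVessel * (1 - exp(-k * tmin * 60))
  obs <- withSeed(seed, {
    if (noiseSd > 0) pmax(ideal + rnorm(length(ideal), 0, noiseSd), 0)
    else ideal
  })
  out <- data.frame(time = tmin, intensity = obs)
  attr(out, "pTrue") <- pTrue
  attr(out, "sOverV") <- sOverV
  attr(out, "iVessel") <- iVessel
  out
}

#' Generate a synthetic tumorsphere brightfield series
#'
#' Renders one sphere per day as a dark disk on a bright background whose
#' true area grows linearly: `area(day) = initialArea + growthRate * day`.
#'
#' @param initialArea sphere area at day 0 in µm² (> 0).
#' @param growthRate linear growth rate in µm²/day.
#' @param days number of days imaged after day 0 (>= 1).
#' @param pixelSize µm per pixel.
#' @param background,foreground brightfield background (bright) and sphere
#'   (dark) intensities.
#' @param noiseSd Gaussian pixel noise SD.
#' @param seed integer RNG seed.
#' @return A list with `stack` (an [ImageStack-class], one frame per day
#'   0..days) and `trueAreas` (data.frame `day`, `area`).
#' @export
generateTumorsphereSeries <- function(initialArea = 1000, growthRate = 500,
                                      days = 7, pixelSize = 2,
                                      background = 200, foreground = 80,
                                      noiseSd = 3, seed = 1L) {
  stopIfNot(initialArea > 0, "initialArea must be > 0")
  stopIfNot(days >= 1, "days must be >= 1")
  areas <- initialArea + growthRate * (0:days)
  if (any(areas <= 0)) stop("invalid spec: growth rate drives area <= 0")
  rmaxPx <- sqrt(max(areas) / pi) / pixelSize
  n <- as.integer(2 * ceiling(rmaxPx) + 21)
  ctr <- (n - 1) / 2
  withSeed(seed, {
    stack <- array(0, c(n, n, 1L, days + 1L))
    for (d in 0:days) {
      r <- sqrt(areas[d + 1] / pi) / pixelSize
      img <- matrix(background, n, n)
      img <- fillEllipse(img, ctr, ctr, r, r, foreground)
      if (noiseSd > 0) img <- img + rnorm(length(img), 0, noiseSd)
      stack[, , 1L, d + 1L] <- img
    }
    list(stack = imageStack(stack, pixelSize = pixelSize,
                            channelNames = "brightfield",
                            metadata = list(days = 0:days, seed = seed)),
         trueAreas = data.frame(day = 0:days, area = areas))
  })
}
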