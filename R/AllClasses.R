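#' @import methods
#' @importFrom stats median mad quantile rnorm runif lm coef p.adjust prcomp
#'   pnorm pwilcox sd complete.cases setNames
#' @importFrom utils combn head read.csv write.csv packageVersion
NULL

# ---------------------------------------------------------------------------
# DeviceGeometry
# ---------------------------------------------------------------------------

#' Microcapillary device geometry
#'
#' Describes a constriction device consisting of sequential constrictive
#' channels (CC) of strictly decreasing width, each followed by an open
#' relaxation chamber (RC). Regions are laid out along the flow axis (x) as
#' `BASELINE, CC_30, RC_30, CC_20, RC_20, CC_10, RC_10, CC_5, RC_5` (labels
#' derive from the widths supplied). The BASELINE interval upstream of the
#' first channel is where undeformed cells are imaged.
#'
#' @slot channelWidths numeric, channel widths in µm, strictly decreasing.
#' @slot channelLength numeric, length of each constrictive channel (µm).
#' @slot channelHeight numeric, channel height (µm); metadata only.
#' @slot spacing numeric, length of each relaxation chamber (µm).
#' @slot pixelSize numeric, µm per pixel for rendered frames.
#' @slot regionTable data.frame with columns `region`, `xmin`, `xmax` (µm),
#'   non-overlapping ordered intervals along the flow axis.
#'
#' @seealso [deviceGeometry()], [regionIntervals()], [assignRegion()]
#' @export
setClass("DeviceGeometry",
  representation(
    channelWidths = "numeric",
    channelLength = "numeric",
    channelHeight = "numeric",
    spacing       = "numeric",
    pixelSize     = "numeric",
    regionTable   = "data.frame"
  )
)

setValidity("DeviceGeometry", function(object) {
  w <- object@channelWidths
  msg <- character()
  if (length(w) < 1L || any(!is.finite(w)) || any(w <= 0))
    msg <- c(msg, "channel widths must be positive and finite")
  if (length(w) > 1L && any(diff(w) >= 0))
    msg <- c(msg, "channel widths must be strictly decreasing")
  for (s in c("channelLength", "channelHeight", "spacing", "pixelSize")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(msg) == 0 && any(w < object@pixelSize))
    msg <- c(msg, "narrowest channel is below one pixel; decrease pixelSize")
  rt <- object@regionTable
  if (nrow(rt) > 1L && any(rt$xmin[-1L] < rt$xmax[-nrow(rt)]))
    msg <- c(msg, "region intervals must be ordered and non-overlapping")
  if (length(msg)) msg else TRUE
})

#' Construct a DeviceGeometry
#'
#' Defaults follow the standard design: four channel sets of 30, 20, 10 and
#' 5 µm width, each 150 µm long and 15 µm high, with 150 µm relaxation
#' chambers in between.
#'
#' @param channelWidths channel widths in µm, strictly decreasing.
#' @param channelLength channel length in µm.
#' @param channelHeight channel height in µm (metadata only; rendering is 2D).
#' @param spacing relaxation-chamber length in µm.
#' @param pixelSize µm per pixel used when rendering frames.
#' @return A [DeviceGeometry-class] object.
#' @examples
#' geom <- deviceGeometry()
#' regionIntervals(geom)
#' @export
deviceGeometry <- function(channelWidths = c(30, 20, 10, 5),
                           channelLength = 150,
                           channelHeight = 15,
                           spacing = 150,
                           pixelSize = 0.5) {
  if (any(channelWidths <= 0))
    stop("invalid geometry: channel widths must be positive")
  regions <- c("BASELINE",
               as.vector(rbind(paste0("CC_", channelWidths),
                               paste0("RC_", channelWidths))))
  lens <- c(spacing,
            as.vector(rbind(rep(channelLength, length(channelWidths)),
                            rep(spacing, length(channelWidths)))))
  xmax <- cumsum(lens)
  rt <- data.frame(region = regions, xmin = c(0, xmax[-length(xmax)]),
                   xmax = xmax, stringsAsFactors = FALSE)
  new("DeviceGeometry", channelWidths = channelWidths,
      channelLength = channelLength, channelHeight = channelHeight,
      spacing = spacing, pixelSize = pixelSize, regionTable = rt)
}

# ---------------------------------------------------------------------------
# ImageStack
# ---------------------------------------------------------------------------

#' Multi-channel image stack
#'
#' Pixel container for all image data in the package. The array axis contract
#' is fixed as `(y, x, channel, time)`; single-channel or single-frame data
#' still carry all four axes. Pixel indices reported by downstream feature
#' extraction are 0-based `(row, col)` with the origin at the top-left;
#' physical coordinates are `index * pixelSize + origin`.
#'
#' @slot data numeric 4D array, axes `(y, x, channel, time)`.
#' @slot pixelSize numeric, µm per pixel.
#' @slot channelNames character, one name per channel axis entry.
#' @slot origin numeric length-2, physical (y, x) offset in µm of pixel (0,0);
#'   used when a frame covers only part of a device.
#' @slot metadata list of free-form provenance (seed, generator parameters,
#'   corrections applied).
#' @export
setClass("ImageStack",
  representation(
    data         = "array",
    pixelSize    = "numeric",
    channelNames = "character",
    origin       = "numeric",
    metadata     = "list"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 4L)
    msg <- c(msg, "data must be a 4D array (y, x, channel, time)")
  else if (dim(d)[3L] != length(object@channelNames))
    msg <- c(msg, "channelNames length must match the channel axis")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be length 2 (y, x)")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param data a matrix (single frame, single channel) or array with up to
#'   four dimensions; trailing channel/time axes of length one are added.
#' @param pixelSize µm per pixel.
#' @param channelNames channel names; defaults to `ch1, ch2, ...`.
#' @param origin physical (y, x) offset in µm of pixel (0, 0).
#' @param metadata free-form provenance list.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(data, pixelSize = 1, channelNames = NULL,
                       origin = c(0, 0), metadata = list()) {
  d <- as.array(data)
  nd <- length(dim(d))
  if (nd < 2L || nd > 4L) stop("data must have 2 to 4 dimensions")
  if (nd < 4L) dim(d) <- c(dim(d), rep(1L, 4L - nd))
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(dim(d)[3L]))
  new("ImageStack", data = d, pixelSize = pixelSize,
      channelNames = channelNames, origin = as.numeric(origin),
      metadata = metadata)
}

# ---------------------------------------------------------------------------
# IlluminationModel
# ---------------------------------------------------------------------------

#' Flatfield/darkfield illumination model
#'
#' Spatial illumination bias model per fluorescence channel:
#' `observed = truth * flatfield + darkfield`, so a corrected frame is
#' `(observed - darkfield) / flatfield`, clamped at zero. Flatfields are
#' strictly positive with mean ~1 over the field; darkfields are additive
#' and non-negative.
#'
#' @slot flatfield named list of matrices (one per channel), mean ~1.
#' @slot darkfield named list of matrices, non-negative.
#' @slot metadata list (estimation details, warnings).
#' @export
setClass("IlluminationModel",
  representation(flatfield = "list", darkfield = "list", metadata = "list")
)

setValidity("IlluminationModel", function(object) {
  msg <- character()
  if (!identical(names(object@flatfield), names(object@darkfield)))
    msg <- c(msg, "flatfield and darkfield channel names must match")
  for (ch in names(object@flatfield)) {
    f <- object@flatfield[[ch]]
    if (any(f <= 0)) msg <- c(msg, sprintf("flatfield[%s] must be > 0", ch))
    else if (abs(mean(f) - 1) > 0.05)
      msg <- c(msg, sprintf("flatfield[%s] mean must be ~1", ch))
    if (any(object@darkfield[[ch]] < 0))
      msg <- c(msg, sprintf("darkfield[%s] must be >= 0", ch))
  }
  if (length(msg)) msg else TRUE
})

illuminationModel <- function(flatfield, darkfield, metadata = list()) {
  new("IlluminationModel", flatfield = flatfield, darkfield = darkfield,
      metadata = metadata)
}

# ---------------------------------------------------------------------------
# LabelMask
# ---------------------------------------------------------------------------

#' Integer-labelled segmentation mask
#'
#' Shares the (y, x) geometry of its source image. Background is 0; object
#' labels are consecutive positive integers.
#'
#' @slot data integer matrix of labels.
#' @slot pixelSize numeric, µm per pixel (inherited from the source image).
#' @slot provenance character, e.g. which channel and operation produced it.
#' @slot flags named list of per-label QC flags (integer label vectors).
#' @export
setClass("LabelMask",
  representation(data = "matrix", pixelSize = "numeric",
                 provenance = "character", flags = "list")
)

setValidity("LabelMask", function(object) {
  labs <- sort(unique(as.integer(object@data)))
  labs <- labs[labs != 0L]
  if (length(labs) && !identical(labs, seq_len(length(labs))))
    return("labels must be consecutive positive integers (background = 0)")
  if (any(object@data < 0)) return("negative labels not allowed")
  TRUE
})

labelMask <- function(data, pixelSize = 1, provenance = "",
                      flags = list()) {
  m <- data
  storage.mode(m) <- "integer"
  new("LabelMask", data = m, pixelSize = pixelSize,
      provenance = provenance, flags = flags)
}

# relabel to consecutive positive integers preserving order of first
# appearance of the original labels
relabelConsecutive <- function(m) {
  labs <- sort(unique(as.integer(m)))
  labs <- labs[labs != 0L]
  if (!length(labs)) {
    storage.mode(m) <- "integer"
    return(m)
  }
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- m
  pos <- m > 0
  out[pos] <- lut[as.integer(m[pos])]
  storage.mode(out) <- "integer"
  out
}
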