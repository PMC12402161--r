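#' @name accessors
#' @title Accessors for CellSqueeze classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object a CellSqueeze S4 object.
#' @param x a CellSqueeze S4 object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(object) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("stackOrigin", function(object) standardGeneric("stackOrigin"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))
#' @rdname accessors
#' @export
setGeneric("maskFlags", function(object) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setGeneric("flatfield", function(object) standardGeneric("flatfield"))
#' @rdname accessors
#' @export
setGeneric("darkfield", function(object) standardGeneric("darkfield"))
#' @rdname accessors
#' @export
setGeneric("regionIntervals", function(object) standardGeneric("regionIntervals"))
#' @rdname accessors
#' @export
setGeneric("channelWidths", function(object) standardGeneric("channelWidths"))

#' @rdname accessors
#' @export
setMethod("imgData", "ImageStack", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LabelMask", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "DeviceGeometry", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("channelNames", "ImageStack", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("stackOrigin", "ImageStack", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("maskData", "LabelMask", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("nLabels", "LabelMask", function(object) {
  m <- max(object@data)
  as.integer(m)
})
#' @rdname accessors
#' @export
setMethod("maskFlags", "LabelMask", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("flatfield", "IlluminationModel", function(object) object@flatfield)
#' @rdname accessors
#' @export
setMethod("darkfield", "IlluminationModel", function(object) object@darkfield)
#' @rdname accessors
#' @export
setMethod("regionIntervals", "DeviceGeometry", function(object) object@regionTable)
#' @rdname accessors
#' @export
setMethod("channelWidths", "DeviceGeometry", function(object) object@channelWidths)

setMethod("show", "DeviceGeometry", function(object) {
  cat("DeviceGeometry:", length(object@channelWidths), "channel sets (",
      paste(object@channelWidths, collapse = "/"), "µm )\n")
  cat("  channel length", object@channelLength, "µm, height",
      object@channelHeight, "µm, spacing", object@spacing, "µm\n")
  cat("  flow-axis extent", max(object@regionTable$xmax), "µm,",
      nrow(object@regionTable), "regions, pixel size",
      object@pixelSize, "µm\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d px, %d channel(s) [%s], %d frame(s)\n",
              d[1], d[2], d[3],
              paste(object@channelNames, collapse = ", "), d[4]))
  cat(sprintf("  pixel size %g µm, origin (%g, %g) µm\n",
              object@pixelSize, object@origin[1], object@origin[2]))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d label(s)%s\n",
              nrow(object@data), ncol(object@data), max(object@data),
              if (nzchar(object@provenance))
                paste0(" [", object@provenance, "]") else ""))
})

setMethod("show", "IlluminationModel", function(object) {
  cat("IlluminationModel for channels:",
      paste(names(object@flatfield), collapse = ", "), "\n")
})
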