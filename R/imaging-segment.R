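# Segmentation: nuclei by MCE thresholding (optionally split by
# distance-transform watershed), cell bodies by nucleus-seeded propagation,
# cytoplasm by per-label subtraction, spheres by blob thresholding.

#' Segment nuclei from a DAPI image
#'
#' Foreground is `pixels > MCE threshold`; connected components are
#' labelled, components smaller than `minArea` are removed, and (optionally)
#' touching nuclei are split by a watershed on the foreground distance
#' transform, whose maxima act as seeds.
#'
#' @param img illumination-corrected DAPI image (matrix or
#'   [ImageStack-class]).
#' @param pixelSize µm per pixel (taken from the stack when `img` is one).
#' @param minArea minimum object area in µm².
#' @param splitTouching split touching nuclei via distance-transform
#'   watershed.
#' @param tolerance watershed tolerance: minimum height separating two
#'   seeds, acting as the minimum seed separation (larger = fewer splits).
#' @param channel,frame selectors when `img` is a stack.
#' @return A [LabelMask-class]; zero labels when the foreground is empty.
#' @export
segmentNuclei <- function(img, pixelSize = NULL, minArea = 20,
                          splitTouching = TRUE, tolerance = 1,
                          channel = "DAPI", frame = 1L) {
  if (is(img, "ImageStack")) {
    if (is.null(pixelSize)) pixelSize <- pixelSize(img)
    if (is.character(channel) && !channel %in% channelNames(img)) channel <- 1L
  }
  if (is.null(pixelSize)) pixelSize <- 1
  m <- getFrame(img, channel, frame)
  thr <- tryCatch(mceThreshold(m), error = function(e) NA_real_)
  if (is.na(thr))
    return(labelMask(matrix(0L, nrow(m), ncol(m)), pixelSize,
                     provenance = "segmentNuclei[constant image]"))
  fg <- m > thr
  if (!any(fg))
    return(labelMask(matrix(0L, nrow(m), ncol(m)), pixelSize,
                     provenance = "segmentNuclei"))
  if (splitTouching) {
    dm <- EBImage::distmap(fg)
    lab <- EBImage::watershed(dm, tolerance = tolerance)
  } else {
    lab <- EBImage::bwlabel(fg)
  }
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes * pixelSize^2 < minArea)
  if (length(drop)) lab[lab %in% drop] <- 0L
  labelMask(relabelConsecutive(lab), pixelSize, provenance = "segmentNuclei")
}

#' Segment cell bodies by nucleus-seeded propagation
#'
#' Foreground comes from the MCE threshold of the body (e.g. actin) channel,
#' augmented with all nuclear pixels; each foreground pixel is assigned to
#' the nucleus seed it reaches by marker-controlled propagation on the body
#' intensity. Cell labels equal their seeding nucleus labels, so the two
#' masks stay aligned. Foreground components containing no nucleus receive
#' no label (they are discarded). A nucleus falling entirely outside the
#' body foreground yields a cell equal to the nucleus itself and is flagged
#' (`nucleusOnly`); labels touching the image border are flagged (`border`)
#' but kept, so downstream QC can drop them.
#'
#' @param img body-channel image (matrix or [ImageStack-class]).
#' @param nuclei nucleus [LabelMask-class] aligned with `img`.
#' @param lambda propagation regularization (weight of geometric distance
#'   against intensity difference; see `EBImage::propagate`).
#' @param channel,frame selectors when `img` is a stack.
#' @return A [LabelMask-class] of cell bodies.
#' @export
segmentCells <- function(img, nuclei, lambda = 1e-4,
                         channel = "ACTIN", frame = 1L) {
  stopIfNot(is(nuclei, "LabelMask"), "nuclei must be a LabelMask")
  if (is(img, "ImageStack") && is.character(channel) &&
      !channel %in% channelNames(img)) channel <- 1L
  m <- getFrame(img, channel, frame)
  nuc <- maskData(nuclei)
  stopIfNot(identical(dim(m), dim(nuc)), "nuclei mask does not match image")
  if (max(nuc) == 0L)
    return(labelMask(matrix(0L, nrow(m), ncol(m)), pixelSize(nuclei),
                     provenance = "segmentCells"))
  thr <- tryCatch(mceThreshold(m), error = function(e) NA_real_)
  fg <- if (is.na(thr)) nuc > 0 else (m > thr) | (nuc > 0)
  cells <- as.matrix(EBImage::propagate(m, seeds = nuc, mask = fg,
                                        lambda = lambda))
  storage.mode(cells) <- "integer"
  labs <- seq_len(max(nuc))
  cellArea <- tabulate(cells[cells > 0], nbins = max(nuc))
  nucArea <- tabulate(nuc[nuc > 0], nbins = max(nuc))
  flags <- list()
  nucOnly <- labs[cellArea <= nucArea]
  if (length(nucOnly)) flags$nucleusOnly <- nucOnly
  border <- sort(unique(c(cells[1, ], cells[nrow(cells), ],
                          cells[, 1], cells[, ncol(cells)])))
  border <- border[border > 0]
  if (length(border)) flags$border <- border
  labelMask(cells, pixelSize(nuclei), provenance = "segmentCells",
            flags = flags)
}

#' Derive cytoplasm labels by subtracting nuclei from cell bodies
#'
#' Requires the two masks to share labels (as produced by [segmentCells()]):
#' cytoplasm label i is cell i minus all nuclear pixels, so per label
#' `area(cell) = area(nucleus) + area(cytoplasm)` exactly. Labels whose
#' cytoplasm is empty (nucleus fills the cell) are flagged.
#'
#' @param cells,nuclei aligned [LabelMask-class] objects.
#' @return A cytoplasm [LabelMask-class] carrying an `emptyCytoplasm` flag
#'   when applicable.
#' @export
deriveCytoplasm <- function(cells, nuclei) {
  stopIfNot(is(cells, "LabelMask") && is(nuclei, "LabelMask"),
            "cells and nuclei must be LabelMasks")
  cm <- maskData(cells); nm <- maskData(nuclei)
  stopIfNot(identical(dim(cm), dim(nm)), "mask shapes differ")
  cyto <- cm
  cyto[nm > 0] <- 0L
  flags <- list()
  if (max(cm) > 0) {
    have <- tabulate(cyto[cyto > 0], nbins = max(cm))
    all0 <- tabulate(cm[cm > 0], nbins = max(cm))
    empty <- which(have == 0 & all0 > 0)
    if (length(empty)) flags$emptyCytoplasm <- empty
  }
  labelMask(cyto, pixelSize(cells), provenance = "deriveCytoplasm",
            flags = flags)
}

#' Segment tumorspheres from a brightfield image
#'
#' Blob detection by MCE thresholding (dark or bright polarity), hole
#' filling and connected-component labelling; areas are returned in µm².
#'
#' @param img brightfield image (matrix or [ImageStack-class]).
#' @param pixelSize µm per pixel.
#' @param polarity `"dark"` for dark spheres on a bright background (the
#'   usual brightfield appearance) or `"bright"`.
#' @param minArea minimum sphere area in µm².
#' @param channel,frame selectors when `img` is a stack.
#' @return A list with `mask` (a [LabelMask-class]) and `areas`
#'   (data.frame `label`, `area_um2`, sorted by label).
#' @export
segmentSpheres <- function(img, pixelSize = NULL, polarity = c("dark", "bright"),
                           minArea = 100, channel = 1L, frame = 1L) {
  polarity <- match.arg(polarity)
  if (is(img, "ImageStack") && is.null(pixelSize)) pixelSize <- pixelSize(img)
  if (is.null(pixelSize)) pixelSize <- 1
  m <- getFrame(img, channel, frame)
  thr <- tryCatch(mceThreshold(m), error = function(e) NA_real_)
  if (is.na(thr)) {
    mask <- labelMask(matrix(0L, nrow(m), ncol(m)), pixelSize,
                      provenance = "segmentSpheres")
    return(list(mask = mask,
                areas = data.frame(label = integer(), area_um2 = numeric())))
  }
  fg <- if (polarity == "dark") m < thr else m > thr
  fg <- as.matrix(EBImage::fillHull(fg))
  lab <- as.matrix(EBImage::bwlabel(fg))
  storage.mode(lab) <- "integer"
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes * pixelSize^2 < minArea)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabelConsecutive(lab)
  }
  mask <- labelMask(lab, pixelSize, provenance = "segmentSpheres")
  nl <- max(lab)
  areas <- if (nl > 0)
    data.frame(label = seq_len(nl),
               area_um2 = tabulate(lab[lab > 0], nbins = nl) * pixelSize^2)
  else data.frame(label = integer(), area_um2 = numeric())
  list(mask = mask, areas = areas)
}
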