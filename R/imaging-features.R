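# Per-object feature extraction: areas, centroids, second-moment ellipse
# axes, and per-channel per-compartment intensities.
#
# Coordinate contract: 0-based pixel indices, (row, col) order, origin at
# the top-left; physical coordinates = index * pixelSize (+ stack origin).
# Major/minor axis lengths come from the ellipse with the same normalized
# second central moments as the pixel set: axis = 4 * sqrt(eigenvalue).

# per-label sums of `values` (same length as labels vector), for labels 1..n
labelSums <- function(labels, values, n) {
  keep <- labels > 0L
  if (!any(keep)) return(numeric(n))
  s <- rowsum(values[keep], labels[keep])
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# moment-ellipse features for every label in an integer matrix
momentEllipse <- function(mask, n) {
  ys <- row(mask) - 1; xs <- col(mask) - 1
  lv <- as.integer(mask)
  area <- labelSums(lv, rep(1, length(lv)), n)
  cy <- labelSums(lv, as.vector(ys), n) / area
  cx <- labelSums(lv, as.vector(xs), n) / area
  syy <- labelSums(lv, as.vector(ys)^2, n) / area - cy^2
  sxx <- labelSums(lv, as.vector(xs)^2, n) / area - cx^2
  sxy <- labelSums(lv, as.vector(ys) * as.vector(xs), n) / area - cy * cx
  tr <- syy + sxx
  det <- syy * sxx - sxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  data.frame(label = seq_len(n), area_px = area,
             centroid_y_px = cy, centroid_x_px = cx,
             major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
             eccentricity = ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0))
}

#' Extract per-cell region features
#'
#' One row per cell label: compartment areas, centroid, moment-ellipse axis
#' lengths and eccentricity, and per-channel mean and integrated intensity
#' in each available compartment. Physical units use the mask's pixel size.
#' Cells whose body touches the image border are flagged `qc_border`
#' (exclude them before shape statistics); empty compartments yield `NA`
#' means and a `qc_empty_cytoplasm` flag.
#'
#' @param cells cell-body [LabelMask-class].
#' @param channels named list of intensity matrices, or an
#'   [ImageStack-class] (its channels are used by name).
#' @param nuclei,cytoplasm optional [LabelMask-class] objects sharing the
#'   cell labels (as produced by [segmentCells()] and [deriveCytoplasm()]).
#' @param origin physical (y, x) offset in µm added to centroid coordinates
#'   (taken from the stack when `channels` is an [ImageStack-class]).
#' @param frame frame selector when `channels` is a stack.
#' @return A data.frame, one row per label.
#' @export
extractFeatures <- function(cells, channels = NULL, nuclei = NULL,
                            cytoplasm = NULL, origin = NULL, frame = 1L) {
  stopIfNot(is(cells, "LabelMask"), "cells must be a LabelMask")
  ps <- pixelSize(cells)
  cm <- maskData(cells)
  n <- max(cm)
  chImgs <- list()
  if (is(channels, "ImageStack")) {
    if (is.null(origin)) origin <- stackOrigin(channels)
    for (ch in channelNames(channels))
      chImgs[[ch]] <- getFrame(channels, ch, frame)
  } else if (is.list(channels)) {
    chImgs <- channels
  }
  if (is.null(origin)) origin <- c(0, 0)
  if (n == 0L) return(data.frame(label = integer()))

  feat <- momentEllipse(cm, n)
  out <- data.frame(label = feat$label,
                    area_cell_um2 = feat$area_px * ps^2,
                    centroid_y_px = feat$centroid_y_px,
                    centroid_x_px = feat$centroid_x_px,
                    centroid_y_um = feat$centroid_y_px * ps + origin[1],
                    centroid_x_um = feat$centroid_x_px * ps + origin[2],
                    major_um = feat$major_px * ps,
                    minor_um = feat$minor_px * ps,
                    eccentricity = feat$eccentricity)
  comps <- list(cell = cm)
  if (!is.null(nuclei)) {
    nm <- maskData(nuclei)
    stopIfNot(identical(dim(nm), dim(cm)), "nuclei mask shape differs")
    comps$nucleus <- nm
    out$area_nucleus_um2 <- labelSums(as.integer(nm),
                                      rep(1, length(nm)), n) * ps^2
  }
  if (!is.null(cytoplasm)) {
    ym <- maskData(cytoplasm)
    stopIfNot(identical(dim(ym), dim(cm)), "cytoplasm mask shape differs")
    comps$cytoplasm <- ym
    out$area_cytoplasm_um2 <- labelSums(as.integer(ym),
                                        rep(1, length(ym)), n) * ps^2
  }
  for (ch in names(chImgs)) {
    v <- as.vector(chImgs[[ch]])
    stopIfNot(length(v) == length(cm), "channel image shape differs")
    for (cp in names(comps)) {
      lv <- as.integer(comps[[cp]])
      tot <- labelSums(lv, v, n)
      cnt <- labelSums(lv, rep(1, length(lv)), n)
      out[[paste0("integrated_", ch, "_", cp)]] <- tot
      out[[paste0("mean_", ch, "_", cp)]] <- ifelse(cnt > 0, tot / cnt, NA)
    }
  }
  fl <- maskFlags(cells)
  out$qc_border <- out$label %in% fl$border
  emptyCyto <- if (!is.null(cytoplasm)) maskFlags(cytoplasm)$emptyCytoplasm
               else integer()
  out$qc_empty_cytoplasm <- out$label %in% emptyCyto
  out
}
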